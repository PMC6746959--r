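# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed from a master seed and a string key, so
# per-region results do not depend on evaluation order.
derive_seed <- function(seed, key) {
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Exact hypergeometric upper tail
#'
#' Closed form of the carrier permutation null: with `k` carriers assigned
#' uniformly without replacement among `n_total` individuals of whom
#' `n_case` are cases, the probability of at least `k_case` carriers landing
#' in cases, `P(X >= k_case)` for `X ~ Hypergeometric(n_total, n_case, k)`.
#'
#' @param k_case observed case carriers, `0 <= k_case <= k`.
#' @param k total carriers.
#' @param n_case number of cases.
#' @param n_total total cohort size.
#' @return probability in (0, 1\].
#' @export
#' @examples
#' # all six carriers among cases, discovery + WES-replication scale
#' hypergeom_upper_tail(6, 6, 2458, 6913)
hypergeom_upper_tail <- function(k_case, k, n_case, n_total) {
  if (k_case < 0 || k < k_case || n_case > n_total || k > n_total) {
    stop("impossible hypergeometric configuration")
  }
  if (k_case == 0) return(1)
  stats::phyper(k_case - 1, n_case, n_total - n_case, k, lower.tail = FALSE)
}

#' Carrier-asymmetry permutation test for a CNV region
#'
#' One-sided test for case excess of region carriers. Null: the
#' `k = k_case + k_control` carrier labels are reassigned uniformly without
#' replacement over all `n_case + n_control` individuals. The Monte Carlo
#' estimate uses the add-one estimator
#' `p_mc = (1 + #\{permutations with case-carrier count >= k_case\}) / (n_perm + 1)`
#' (never zero), with the exact hypergeometric upper tail reported alongside
#' as `p_exact` and the binomial standard error `se_mc`.
#'
#' @param k_case,k_control observed carriers among cases / controls.
#' @param n_case,n_control cohort sizes; defaults are the combined
#'   discovery + WES-replication probands (2,458) and family controls
#'   (4,455).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return list of class `carrier_perm_test`: `k_case`, `k_control`,
#'   `n_case`, `n_control`, `n_perm`, `seed`, `p_mc`, `p_exact`, `se_mc`.
#' @export
carrier_permutation_test <- function(k_case, k_control, n_case = 2458L,
                                     n_control = 4455L, n_perm = 10000L,
                                     seed = 1L) {
  if (any(c(k_case, k_control, n_case, n_control) < 0) || n_perm < 1) {
    stop("counts must be nonnegative and n_perm >= 1")
  }
  if (k_case > n_case || k_control > n_control) {
    stop("carrier counts exceed cohort sizes")
  }
  k <- k_case + k_control
  n_total <- n_case + n_control
  if (k == 0L) {
    warning("zero carriers: p = 1 by convention")
    return(structure(list(k_case = k_case, k_control = k_control,
                          n_case = n_case, n_control = n_control,
                          n_perm = n_perm, seed = seed, p_mc = 1,
                          p_exact = 1, se_mc = 0),
                     class = "carrier_perm_test"))
  }
  counts <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(sample.int(n_total, k) <= n_case), integer(1))
  })
  p_mc <- (1 + sum(counts >= k_case)) / (n_perm + 1)
  structure(list(k_case = k_case, k_control = k_control, n_case = n_case,
                 n_control = n_control, n_perm = n_perm, seed = seed,
                 p_mc = p_mc,
                 p_exact = hypergeom_upper_tail(k_case, k, n_case, n_total),
                 se_mc = sqrt(p_mc * (1 - p_mc) / n_perm)),
            class = "carrier_perm_test")
}

#' @export
print.carrier_perm_test <- function(x, ...) {
  cat(sprintf(
    "carrier permutation test: %d/%d case vs %d/%d control carriers\n  p_mc = %.4g (n_perm = %d, se = %.2g), p_exact = %.4g\n",
    x$k_case, x$n_case, x$k_control, x$n_control, x$p_mc, x$n_perm, x$se_mc,
    x$p_exact))
  invisible(x)
}

#' Attach carrier-asymmetry p-values to a regions table
#'
#' Runs [carrier_permutation_test()] per region with a per-region seed
#' derived from the master seed and the region ID (order-independent), and
#' adds an optional Benjamini-Hochberg column (`p_bh`, informational only:
#' regions are never filtered on it).
#'
#' @param regions regions data.frame.
#' @param n_case,n_control null-population sizes.
#' @param n_perm permutations per region.
#' @param seed master seed.
#' @return regions with `p_carrier` (Monte Carlo), `p_exact`, `se_mc`,
#'   `n_perm`, `seed` and `p_bh` columns.
#' @export
test_regions <- function(regions, n_case, n_control, n_perm = 10000L,
                         seed = 1L) {
  n <- nrow(regions)
  regions$p_carrier <- regions$p_exact <- regions$se_mc <- rep(NA_real_, n)
  regions$n_perm <- rep(as.integer(n_perm), n)
  regions$seed <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- derive_seed(seed, regions$region_id[i])
    res <- carrier_permutation_test(regions$n_case_carriers[i],
                                    regions$n_control_carriers[i],
                                    n_case, n_control, n_perm, s)
    regions$p_carrier[i] <- res$p_mc
    regions$p_exact[i] <- res$p_exact
    regions$se_mc[i] <- res$se_mc
    regions$seed[i] <- s
  }
  regions$p_bh <- if (n) stats::p.adjust(regions$p_exact, "BH") else numeric(0)
  regions
}
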