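test_that("proband call with no relative calls in a genotyped family is de novo", {
  pro <- mk_calls("chr2", 109363161, 109371723, sample_id = "F1-01",
                  family_id = "F1")
  rel <- mk_calls("chr5", 1e6, 2e6, sample_id = "F1-02", family_id = "F1",
                  role = "father", call_id = "rel1")
  v <- classify_inheritance(pro, rel, rho = 0.5, n_relatives = 2L)
  expect_equal(v$verdict, "de_novo")
  expect_equal(v$max_relative_overlap, 0)
})

test_that("identical maternal call makes the proband call inherited", {
  pro <- mk_calls("chr2", 109363161, 109371723, sample_id = "F1-01",
                  family_id = "F1")
  rel <- mk_calls("chr2", 109363161, 109371723, sample_id = "F1-03",
                  family_id = "F1", role = "mother", call_id = "rel1")
  v <- classify_inheritance(pro, rel, rho = 0.5, n_relatives = 2L)
  expect_equal(v$verdict, "inherited")
  expect_equal(v$max_relative_overlap, 1)
  expect_equal(v$matching_relative_calls, "rel1")
})

test_that("no genotyped relatives means unclassified, not de novo", {
  pro <- mk_calls("chr2", 109363161, 109371723, sample_id = "F1-01",
                  family_id = "F1")
  v <- classify_inheritance(pro, cnvtrio:::empty_calls(), n_relatives = 0L)
  expect_equal(v$verdict, "unclassified")
})

test_that("matching ignores DEL/DUP type: a parental DUP blocks a proband DEL", {
  pro <- mk_calls("chr2", 109363161, 109371723, cnv_type = "DEL",
                  sample_id = "F1-01", family_id = "F1")
  rel <- mk_calls("chr2", 109363161, 109371723, cnv_type = "DUP",
                  sample_id = "F1-02", family_id = "F1", role = "father",
                  call_id = "rel1")
  v <- classify_inheritance(pro, rel, n_relatives = 1L)
  expect_equal(v$verdict, "inherited")
})

test_that("relative calls from a different family are a contract violation", {
  pro <- mk_calls("chr2", 1e6, 2e6, sample_id = "F1-01", family_id = "F1")
  rel <- mk_calls("chr2", 1e6, 2e6, sample_id = "F2-02", family_id = "F2",
                  role = "father", call_id = "x")
  expect_error(classify_inheritance(pro, rel, n_relatives = 1L),
               "different family")
})

test_that("verdicts match a brute-force all-pairs enumeration on small cohorts", {
  set.seed(201)
  for (rep in 1:10) {
    iv <- random_ivs(20, max_coord = 1000)
    pro <- mk_calls(iv$chrom[1:10], iv$start[1:10], iv$end[1:10],
                    sample_id = "F1-01", family_id = "F1",
                    call_id = sprintf("p%02d", 1:10))
    rel <- mk_calls(iv$chrom[11:20], iv$start[11:20], iv$end[11:20],
                    sample_id = "F1-02", family_id = "F1", role = "father",
                    call_id = sprintf("r%02d", 1:10))
    for (i in 1:10) {
      v <- classify_inheritance(pro[i, ], rel, rho = 0.5, n_relatives = 1L)
      ro <- vapply(1:10, function(j)
        reciprocal_overlap(pro[i, ], rel[j, ]), 0)
      expect_equal(v$verdict, if (any(ro >= 0.5)) "inherited" else "de_novo")
      expect_equal(v$max_relative_overlap, max(ro))
    }
  }
})

test_that("raising rho can only convert inherited to de novo", {
  set.seed(202)
  rhos <- c(0.2, 0.5, 0.8)
  for (rep in 1:10) {
    iv <- random_ivs(12, max_coord = 500)
    pro <- mk_calls(iv$chrom[1:6], iv$start[1:6], iv$end[1:6],
                    sample_id = "F1-01", family_id = "F1",
                    call_id = sprintf("p%d", 1:6))
    rel <- mk_calls(iv$chrom[7:12], iv$start[7:12], iv$end[7:12],
                    sample_id = "F1-02", family_id = "F1", role = "father",
                    call_id = sprintf("r%d", 1:6))
    for (i in 1:6) {
      verdicts <- vapply(rhos, function(r)
        classify_inheritance(pro[i, ], rel, rho = r, n_relatives = 1L)$verdict,
        "")
      # once de_novo at some rho, must stay de_novo at every larger rho
      first_dn <- match("de_novo", verdicts)
      if (!is.na(first_dn)) {
        expect_true(all(verdicts[first_dn:length(rhos)] == "de_novo"))
      }
    }
  }
})

test_that("verdicts are independent of call ordering", {
  set.seed(203)
  iv <- random_ivs(8, max_coord = 500)
  pro <- mk_calls("chr1", 100, 300, sample_id = "F1-01", family_id = "F1")
  rel <- mk_calls(iv$chrom, iv$start, iv$end, sample_id = "F1-02",
                  family_id = "F1", role = "father",
                  call_id = sprintf("r%d", 1:8))
  v1 <- classify_inheritance(pro, rel, n_relatives = 1L)
  v2 <- classify_inheritance(pro, rel[sample(8), ], n_relatives = 1L)
  expect_equal(v1$verdict, v2$verdict)
  expect_equal(v1$matching_relative_calls, v2$matching_relative_calls)
})

test_that("control filter drops exactly the planted shared calls", {
  # 10 proband-unique calls on chr1, 5 calls shared with a control on chr2
  uniq <- mk_calls("chr1", seq(1e6, by = 2e6, length.out = 10),
                   seq(1e6, by = 2e6, length.out = 10) + 5e4,
                   sample_id = "F1-01", family_id = "F1",
                   call_id = sprintf("u%02d", 1:10))
  shared <- mk_calls("chr2", seq(1e6, by = 2e6, length.out = 5),
                     seq(1e6, by = 2e6, length.out = 5) + 5e4,
                     sample_id = "F1-01", family_id = "F1",
                     call_id = sprintf("s%02d", 1:5))
  ctrl <- shared
  ctrl$call_id <- sprintf("ctl%02d", 1:5)
  ctrl$sample_id <- "F9-02"; ctrl$family_id <- "F9"; ctrl$role <- "father"
  res <- filter_against_controls(rbind(uniq, shared), ctrl, rho = 0.5)
  expect_equal(sort(res$surviving$call_id), sort(uniq$call_id))
  dropped <- res$trace[res$trace$decision == "drop", ]
  expect_equal(nrow(dropped), 5L)
  expect_true(all(grepl("^ctl", dropped$evidence)))
})

test_that("no control overlap lets every call survive", {
  pro <- mk_calls("chr1", c(100, 5000), c(200, 6000), sample_id = "F1-01",
                  family_id = "F1", call_id = c("a", "b"))
  ctrl <- mk_calls("chr2", 100, 200, sample_id = "X", family_id = "X",
                   role = "unrelated_control", call_id = "c")
  res <- filter_against_controls(pro, ctrl)
  expect_equal(nrow(res$surviving), 2L)
  expect_true(all(res$trace$decision == "pass"))
})

test_that("filter_inherited routes verdicts into the de novo channel and trace", {
  ped <- finalize_ped(rbind(trio_ped_rows("F1"),
                            trio_ped_rows("F2", parents = FALSE)))
  calls <- rbind(
    mk_calls("chr1", 100, 2000, sample_id = "F1-01", family_id = "F1",
             call_id = "dn1"),
    mk_calls("chr2", 100, 2000, sample_id = "F1-01", family_id = "F1",
             call_id = "inh1"),
    mk_calls("chr2", 100, 2000, sample_id = "F1-02", family_id = "F1",
             role = "father", call_id = "fa1"),
    mk_calls("chr3", 100, 2000, sample_id = "F2-01", family_id = "F2",
             call_id = "uncl1"))
  res <- filter_inherited(calls, ped)
  expect_equal(res$de_novo$call_id, "dn1")
  v <- res$verdicts
  expect_equal(v$verdict[v$call_id == "inh1"], "inherited")
  expect_equal(v$verdict[v$call_id == "uncl1"], "unclassified")
  expect_equal(sort(res$trace$call_id), sort(c("dn1", "inh1", "uncl1")))
})
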