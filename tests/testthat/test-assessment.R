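# independent quartile/fence oracle: classic Tukey fences Q1 - 1.5*IQR /
# Q3 + 1.5*IQR computed directly from stats::quantile
classic_fences <- function(x) {
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

test_that("fence formulas match the classic Q +/- 1.5*IQR form", {
  f <- tukey_fences(c(1, 2, 3, 4))
  expect_equal(c(f$lower, f$upper), unname(classic_fences(c(1, 2, 3, 4))))
  # all-zero diffs: degenerate but valid, zero lies inside inclusively
  f0 <- tukey_fences(rep(0, 10))
  expect_equal(c(f0$lower, f0$upper), c(0, 0))
  # symmetric diffs give symmetric fences
  fs <- tukey_fences(c(-30, -10, 10, 30))
  expect_equal(fs$lower, -fs$upper)
  expect_error(tukey_fences(c(1, 2, 3)), "at least 4")
  set.seed(13)
  for (i in 1:50) {
    x <- rnorm(sample(4:200, 1), sd = 10^runif(1, 0, 4))
    f <- tukey_fences(x)
    expect_equal(c(f$lower, f$upper), unname(classic_fences(x)),
                 tolerance = 1e-12)
  }
})

test_that("oriented query positions reflect '-' alignments", {
  qry <- mk_map(1, c(30000, 60000), length_bp = 100000)
  ref <- mk_map(2, c(10000, 40000), length_bp = 100000)
  fwd <- mk_aln(1, qry, ref, cbind(1:2, 1:2))
  expect_equal(unname(oriented_query_positions(fwd, qry)), c(30000, 60000))
  rev <- mk_aln(2, qry, ref, cbind(1:2, 2:1), orientation = "-")
  expect_equal(unname(oriented_query_positions(rev, qry)),
               c(100000 - 30000 + 1, 100000 - 60000 + 1))
  # reflection turns strictly decreasing matched positions into increasing
  set.seed(21)
  for (i in 1:20) {
    pos <- sort(sample.int(99999, 5))
    qm <- mk_map(1, pos, length_bp = 1e5)
    a <- mk_aln(1, qm, ref, cbind(1:2, c(5, 1)), orientation = "-")
    op <- oriented_query_positions(a, qm)
    expect_equal(unname(op), 1e5 - pos + 1)
    expect_true(all(diff(op[as.character(c(5, 1))]) > 0) ==
                  all(diff(pos[c(5, 1)]) < 0))
  }
  bad <- mk_aln(3, qry, ref, cbind(1:2, 1:2))
  bad$pairs$qry_site_id <- c(1L, 9L)
  expect_error(oriented_query_positions(bad, qry), "absent")
})

test_that("interval diffs carry distances, sign convention and skip counts", {
  # identical fully matched six-site maps: five diffs, all exactly zero
  ref <- mk_map(1, 1e4 * (1:6))
  qry <- mk_map(2, 1e4 * (1:6))
  iv <- compute_interval_diffs(mk_aln(1, qry, ref, cbind(1:6, 1:6)), ref, qry)
  expect_equal(nrow(iv), 5)
  expect_equal(iv$diff, rep(0, 5))
  expect_equal(iv$skipped_ref_sites, rep(0L, 5))

  # ref interval 10 kb vs qry interval 9 kb -> diff = +1000
  qry2 <- mk_map(2, c(10000, 19000))
  ref2 <- mk_map(1, c(10000, 20000))
  iv2 <- compute_interval_diffs(mk_aln(1, qry2, ref2, cbind(1:2, 1:2)),
                                ref2, qry2)
  expect_equal(iv2$diff, 1000)
  expect_equal(iv2$d_ref, 10000)
  expect_equal(iv2$d_qry, 9000)

  # unmatched ref site between the matched pair -> skipped_ref_sites = 1
  ref3 <- mk_map(1, c(10000, 20000, 30000))
  qry3 <- mk_map(2, c(10000, 30000))
  iv3 <- compute_interval_diffs(mk_aln(1, qry3, ref3, cbind(c(1, 3), 1:2)),
                                ref3, qry3)
  expect_equal(iv3$skipped_ref_sites, 1L)
  expect_equal(iv3$diff, 0)

  # skipped query sites counted too, also under '-' orientation
  qry4 <- mk_map(2, c(10000, 20000, 30000))
  iv4 <- compute_interval_diffs(mk_aln(1, qry4, ref2, cbind(1:2, c(3, 1)),
                                       orientation = "-"), ref2, qry4)
  expect_equal(iv4$skipped_qry_sites, 1L)
  expect_equal(iv4$d_qry, 20000)

  # fewer than 2 pairs: no intervals
  expect_equal(nrow(compute_interval_diffs(
    mk_aln(1, qry2, ref2, cbind(1, 1)), ref2, qry2)), 0)
})

test_that("interval classification covers all five cases inclusively", {
  fences <- tukey_fences(c(-100, -50, 50, 100))
  iv <- data.frame(diff = c(0, fences$lower, fences$upper, -5000, 5000,
                            0, -5000, 5000),
                   skipped_ref_sites = c(0, 0, 0, 0, 0, 2, 1, 1))
  expect_equal(classify_intervals(iv, fences),
               c("OK", "OK", "OK", "MISSING_IN_REF", "EXTRA_IN_REF",
                 "SITE_COUNT_CONFLICT", "COMPLEX", "COMPLEX"))
})

test_that("per-site scoring reproduces the five worked cases", {
  expect_equal(case_site_scores("consistent"), rep(4L, 6))
  expect_equal(case_site_scores("site_conflict"), rep(3L, 3))
  expect_equal(case_site_scores("distance_conflict"), rep(2L, 2))
  expect_equal(case_site_scores("combined_conflict"), rep(1L, 3))
  expect_equal(case_site_scores("uncovered"), rep(0L, 2))
})

test_that("every reference site is scored exactly once", {
  for (case in c("consistent", "site_conflict", "distance_conflict",
                 "combined_conflict", "uncovered")) {
    cs <- scoring_case(case)
    res <- assess_maps(cs$ref_maps, cs$qry_maps, cs$alignments)
    n_sites <- sum(vapply(cs$ref_maps, function(m) nrow(m$sites), 0L))
    expect_equal(nrow(res$site_scores), n_sites)
    expect_equal(anyDuplicated(res$site_scores[, c("ref_map_id", "site_id")]),
                 0L)
    expect_equal(sum(res$case_counts), n_sites)
    expect_true(all(res$site_scores$score %in% 0:4))
  }
})

test_that("a site bounded by two intervals takes the worse score", {
  bg <- background_case()
  ref <- mk_map(2, 1e4 * (1:3))
  # first interval OK, second a gross distance conflict: middle site -> 2
  qry <- mk_map(2, c(10000, 20000, 25000))
  aln <- mk_aln(2, qry, ref, cbind(1:3, 1:3))
  res <- assess_maps(list("1" = bg$ref, "2" = ref),
                     list("1" = bg$qry, "2" = qry),
                     list(bg$aln, aln))
  expect_equal(res$site_scores$score[res$site_scores$ref_map_id == 2],
               c(4L, 2L, 2L))
})

test_that("the higher-confidence alignment wins where alignments overlap", {
  bg <- background_case()
  ref <- mk_map(2, 1e4 * (1:3))
  good <- mk_map(2, 1e4 * (1:3))           # consistent distances
  bad <- mk_map(3, c(10000, 16000, 22000)) # gross conflicts
  a_good <- mk_aln(2, good, ref, cbind(1:3, 1:3), confidence = 40)
  a_bad <- mk_aln(3, bad, ref, cbind(1:3, 1:3), confidence = 12)
  res <- assess_maps(list("1" = bg$ref, "2" = ref),
                     list("1" = bg$qry, "2" = good, "3" = bad),
                     list(bg$aln, a_good, a_bad))
  expect_equal(res$site_scores$score[res$site_scores$ref_map_id == 2],
               rep(4L, 3))
})

test_that("indel calls follow the diff sign on outlier intervals only", {
  fences <- tukey_fences(c(-100, -50, 50, 100))
  iv <- data.frame(diff = c(-5000, 5000, 0, 60),
                   skipped_ref_sites = 0L)
  calls <- call_indels(iv, fences)
  expect_equal(calls$call, c("insertion_in_sample", "deletion_in_sample"))
  expect_equal(calls$size_bp, c(5000, 5000))
  expect_equal(nrow(call_indels(data.frame(diff = 0), fences)), 0)
})

test_that("reliability flags follow the coverage/confidence heuristic", {
  ss <- data.frame(ref_map_id = 1L, site_id = 1:4, position_bp = 1:4 * 1e4,
                   score = c(2L, 2L, 4L, 2L),
                   coverage = c(40, 5, 1, 5),
                   confidence = c(50, 8, NA, 15),
                   reliability = NA_character_)
  out <- reliability_flags(ss, mean_coverage = 20)
  expect_equal(out$reliability,
               c("supported",            # questionable, coverage > mean
                 "needs_verification",   # low coverage, confidence 8 < 10
                 "supported",            # score 4: supported regardless
                 "supported"))           # low coverage but confidence >= 10
  expect_error(reliability_flags(ss, -1), "mean_coverage")
})

test_that("regions merge adjacent same-class intervals and unmapped runs", {
  bg <- background_case()
  # two consecutive gross-conflict intervals, then a clean one
  ref <- mk_map(2, 1e4 * (1:4))
  qry <- mk_map(2, c(10000, 15000, 20000, 30000))
  aln <- mk_aln(2, qry, ref, cbind(1:4, 1:4))
  res <- assess_maps(list("1" = bg$ref, "2" = ref),
                     list("1" = bg$qry, "2" = qry),
                     list(bg$aln, aln),
                     key_table = data.frame(name = c("bg", "ctgA"),
                                            cmap_id = 1:2))
  reg <- res$regions[res$regions$ref_map_id == 2, ]
  expect_equal(nrow(reg), 1)  # the two EXTRA intervals merged
  expect_equal(reg$category, "EXTRA_IN_REF")
  expect_equal(reg$start_bp, 10000)
  expect_equal(reg$end_bp, 30000)
  expect_equal(reg$ref_name, "ctgA")
  expect_equal(reg$mean_diff_bp, 5000)

  # an uncovered tail becomes one UNMAPPED region spanning its sites
  cs <- scoring_case("uncovered")
  res2 <- assess_maps(cs$ref_maps, cs$qry_maps, cs$alignments)
  unm <- res2$regions[res2$regions$category == "UNMAPPED", ]
  expect_equal(nrow(unm), 1)
  expect_equal(c(unm$start_bp, unm$end_bp), c(10000, 20000))
})

test_that("QQ R-squared flags outliers and trimming restores normality", {
  set.seed(77)
  clean <- rnorm(400, 0, 150)
  f <- tukey_fences(clean)
  rep_clean <- diff_normality(clean, f)
  expect_gt(rep_clean$r_squared_after, 0.95)
  # 5% gross outliers wreck the fit; trimming repairs it
  dirty <- c(rnorm(380, 0, 150), runif(20, 5000, 20000))
  fd <- tukey_fences(dirty)
  rep_dirty <- diff_normality(dirty, fd)
  expect_lt(rep_dirty$r_squared_before, rep_dirty$r_squared_after)
  expect_equal(rep_dirty$n_total, 400)
  expect_lt(rep_dirty$n_trimmed, 400)
  # constant diffs: R^2 is 1 by convention
  fc <- tukey_fences(rep(2, 10))
  expect_equal(diff_normality(rep(2, 10), fc)$r_squared_after, 1)
  expect_error(diff_normality(rnorm(5), f), "at least 8")
})

test_that("fence boundary formulas are the classic fences, algebraically", {
  set.seed(14)
  for (i in 1:100) {
    q1 <- runif(1, -100, 100)
    q3 <- q1 + runif(1, 0, 200)
    expect_equal(2.5 * q1 - 1.5 * q3, q1 - 1.5 * (q3 - q1))
    expect_equal(2.5 * q3 - 1.5 * q1, q3 + 1.5 * (q3 - q1))
  }
})
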