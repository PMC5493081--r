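bspqi <- get_enzyme("Nt.BspQI")

test_that("simulated genomes are deterministic and hit the target density", {
  g1 <- simulate_genome(1e5, bspqi, 11, seed = 3)
  g2 <- simulate_genome(1e5, bspqi, 11, seed = 3)
  expect_identical(g1, g2)
  expect_error(simulate_genome(5000, bspqi), "10 kb")
  expect_error(simulate_genome(1e5, bspqi, 2e4), "spacing")
  # density within +/-20% of target across a few seeds (1 Mb, 11/100 kb)
  for (s in 1:3) {
    g <- simulate_genome(1e6, bspqi, 11, seed = s)
    n <- length(find_nick_sites(g, bspqi))
    expect_gte(n, 88)
    expect_lte(n, 132)
  }
})

test_that("doubling the density about doubles the mean site count", {
  counts <- function(dens) vapply(1:8, function(s)
    length(find_nick_sites(simulate_genome(1e5, bspqi, dens, seed = s),
                           bspqi)), 0L)
  ratio <- mean(counts(22)) / mean(counts(11))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("misassembly injection edits lengths by the signed event sizes", {
  set.seed(60)
  g <- simulate_genome(1e5, bspqi, 11)
  # single 20 kb deletion
  del <- inject_misassemblies(g, data.frame(kind = "deletion",
                                            start_bp = 30000,
                                            size_bp = 20000))
  expect_equal(nchar(del$sequence), 1e5 - 20000)
  expect_equal(del$events$kind, "deletion")
  # no events: unchanged
  expect_identical(inject_misassemblies(g)$sequence, g)
  # mixed random events: length change = signed sum
  ev <- data.frame(kind = c("deletion", "insertion", "deletion", "insertion"),
                   start_bp = c(10000, 35000, 50000, 80000),
                   size_bp = c(3000, 4000, 2000, 1500))
  out <- inject_misassemblies(g, ev)
  expect_equal(nchar(out$sequence), 1e5 - 3000 + 4000 - 2000 + 1500)
  # realized insertion spans hold the inserted (label-free) sequence
  ins <- out$events[out$events$kind == "insertion", ]
  for (i in seq_len(nrow(ins))) {
    piece <- substr(out$sequence, ins$start_bp[i], ins$end_bp[i])
    expect_equal(nchar(piece), ins$size_bp[i])
    expect_length(find_nick_sites(piece, bspqi), 0)
  }
  expect_error(inject_misassemblies(g, data.frame(
    kind = "deletion", start_bp = c(1000, 1500), size_bp = c(1000, 100))),
    "overlap")
})

test_that("the genome-to-assembly coordinate map is consistent", {
  set.seed(61)
  g <- simulate_genome(5e4, bspqi, 11)
  ev <- data.frame(kind = c("deletion", "insertion"),
                   start_bp = c(10000, 30000), size_bp = c(2000, 3000))
  out <- inject_misassemblies(g, ev)
  pos <- c(5000, 9999, 10500, 12000, 29999, 30000, 45000)
  mapped <- map_genome_to_assembly(out$coord_map, pos)
  expect_equal(mapped[2], 9999)           # before the deletion: unchanged
  expect_true(is.na(mapped[3]))           # inside the deletion: gone
  expect_equal(mapped[4], 12000 - 2000)   # after the deletion: shifted left
  expect_equal(mapped[7], 45000 - 2000 + 3000)  # after both events
  # every mapped base carries the same nucleotide
  ok <- !is.na(mapped)
  expect_equal(substring(out$sequence, mapped[ok], mapped[ok]),
               substring(g, pos[ok], pos[ok]))
})

test_that("misplacement moves a block and records its destination", {
  set.seed(62)
  g <- simulate_genome(5e4, bspqi, 11)
  out <- inject_misassemblies(g, data.frame(kind = "misplacement",
                                            start_bp = 10000, size_bp = 5000,
                                            dest_bp = 40000))
  expect_equal(nchar(out$sequence), nchar(g))
  ev <- out$events
  expect_equal(ev$kind, "misplacement")
  expect_equal(substr(out$sequence, ev$start_bp, ev$end_bp),
               substr(g, 10000, 14999))
})

test_that("query-map simulation: zero noise reproduces reference windows", {
  set.seed(63)
  g <- simulate_genome(3e5, bspqi, 11)
  gmap <- digest_fasta(c(ctg = g), bspqi)$maps[[1]]
  sim <- suppressWarnings(
    simulate_query_maps(gmap, sizing_sd_fraction = 0,
                        site_dropout_prob = 0, false_label_rate = 0,
                        fragment_length_bp = 100000))
  # every reference site survives in at least one fragment
  expect_setequal(unique(sim$correspondence$ref_site_id),
                  gmap$sites$site_id)
  # site offsets equal reference offsets within each fragment
  for (qid in names(sim$qry_maps)) {
    frag <- sim$fragments[sim$fragments$qry_map_id == as.integer(qid), ]
    corr <- sim$correspondence[sim$correspondence$qry_map_id ==
                                 as.integer(qid), ]
    qm <- sim$qry_maps[[qid]]
    qpos <- qm$sites$position_bp[match(corr$qry_site_id, qm$sites$site_id)]
    rpos <- gmap$sites$position_bp[match(corr$ref_site_id,
                                         gmap$sites$site_id)]
    expect_equal(qpos, rpos - frag$ref_start_bp + 1)
  }
  # interior sites are covered by two fragments at 50% tiling
  cov <- unlist(lapply(sim$qry_maps, function(m) m$sites$coverage))
  expect_true(all(cov %in% 1:2))
  expect_true(any(cov == 2))
})

test_that("site dropout removes about the stated fraction of truth pairs", {
  set.seed(64)
  g <- simulate_genome(1e6, bspqi, 11)
  gmap <- digest_fasta(c(ctg = g), bspqi)$maps[[1]]
  n_pairs <- function(p) {
    sim <- simulate_query_maps(gmap, sizing_sd_fraction = 0,
                               site_dropout_prob = p,
                               fragment_length_bp = 150000)
    nrow(sim$correspondence)
  }
  n0 <- n_pairs(0)
  n10 <- n_pairs(0.1)
  frac <- 1 - n10 / n0
  # binomial with n0 ~ 250 trials: 10% +/- 5 points
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.15)
})

test_that("truth alignments are exact and orientation-aware", {
  set.seed(65)
  g <- simulate_genome(3e5, bspqi, 11)
  gmap <- digest_fasta(c(ctg = g), bspqi)$maps[[1]]
  sim <- simulate_query_maps(gmap, sizing_sd_fraction = 0,
                             fragment_length_bp = 100000, reverse_prob = 1)
  alns <- build_truth_xmap(sim$correspondence, gmap, sim$qry_maps)
  expect_true(all(vapply(alns, `[[`, "", "orientation") == "-"))
  for (a in alns) {
    expect_true(all(diff(a$pairs$ref_site_id) > 0))
    expect_true(all(diff(a$pairs$qry_site_id) < 0))
    expect_equal(a$confidence, 50)
  }
  # noise-free: all diffs are zero whatever the orientation
  iv <- do.call(rbind, lapply(alns, function(a)
    compute_interval_diffs(a, gmap, sim$qry_maps[[as.character(a$qry_map_id)]])))
  expect_equal(iv$diff, rep(0, nrow(iv)))
  # truth alignments survive an XMAP round trip
  path <- withr::local_tempfile(fileext = ".xmap")
  write_xmap(alns, path)
  back <- read_xmap(path)
  for (i in seq_along(alns))
    expect_equal(back[[i]]$pairs, alns[[i]]$pairs)
})

test_that("whole datasets are deterministic under a fixed seed", {
  ds1 <- simulate_dataset(genome_length_bp = 5e4, seed = 99)
  ds2 <- simulate_dataset(genome_length_bp = 5e4, seed = 99)
  expect_identical(ds1$genome, ds2$genome)
  expect_identical(ds1$qry_maps, ds2$qry_maps)
  expect_identical(ds1$alignments, ds2$alignments)
})

test_that("adding a misassembly never decreases the non-OK interval count", {
  events <- data.frame(kind = c("deletion", "insertion", "deletion"),
                       start_bp = c(1e5, 3e5, 5e5), size_bp = c(4000, 4500, 5000))
  n_bad <- vapply(0:3, function(k) {
    ds <- simulate_dataset(genome_length_bp = 7e5,
                           events = if (k) events[seq_len(k), ] else NULL,
                           sizing_sd_fraction = 0.02, seed = 123)
    res <- assess_maps(ds$ref_maps, ds$qry_maps, ds$alignments)
    sum(res$intervals$class != "OK")
  }, 0L)
  expect_true(all(diff(n_bad) >= 0))
})
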