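# Builders for toy maps/alignments and random valid instances used across
# the suite. All randomness is driven by seeds set in the tests.

mk_map <- function(id, positions, length_bp = max(positions) + 5000,
                   coverage = 0, occurrence = 0) {
  restriction_map(id, length_bp,
                  data.frame(site_id = seq_along(positions),
                             position_bp = positions,
                             coverage = rep_len(coverage, length(positions)),
                             occurrence = rep_len(occurrence, length(positions)),
                             std_dev = 0))
}

mk_aln <- function(entry, qry_map, ref_map, pairs, orientation = "+",
                   confidence = 50) {
  pairs <- data.frame(ref_site_id = pairs[, 1], qry_site_id = pairs[, 2])
  rp <- ref_map$sites$position_bp[match(pairs$ref_site_id,
                                        ref_map$sites$site_id)]
  qp <- qry_map$sites$position_bp[match(pairs$qry_site_id,
                                        qry_map$sites$site_id)]
  map_alignment(entry, qry_map$map_id, ref_map$map_id,
                min(qp), max(qp), min(rp), max(rp),
                orientation, confidence, pairs)
}

# Background alignment giving the pooled fences some finite width: 21
# matched sites, 20 conflict-free intervals with diffs spread -100..100 bp.
background_case <- function() {
  jit <- seq(-100, 100, length.out = 20)
  ref <- mk_map(1, 10000 * (1:21))
  qry <- mk_map(1, 5000 + cumsum(c(0, 10000 - jit)))
  list(ref = ref, qry = qry,
       aln = mk_aln(1, qry, ref, cbind(1:21, 1:21)))
}

# The five worked mapping cases: a reference contig of six sites at 10 kb
# spacing aligned to a query map so that the intervals realise, in turn, a
# consistent match, a site-count conflict, a distance conflict, both
# conflicts at once, and an uncovered 5' end. Returns everything needed for
# an assess_maps() run plus the site ids whose score the case is about.
scoring_case <- function(which) {
  cfg <- switch(which,
    consistent = list(qry = 1e4 * (1:6), pairs = cbind(1:6, 1:6),
                      sites = 1:6),
    site_conflict = list(qry = c(10000, 30000, 40000, 50000, 60000),
                         pairs = cbind(c(1, 3:6), 1:5), sites = 1:3),
    distance_conflict = list(qry = c(10000, 25000, 35000, 45000, 55000, 65000),
                             pairs = cbind(1:6, 1:6), sites = 1:2),
    combined_conflict = list(qry = c(10000, 35000, 45000, 55000, 65000),
                             pairs = cbind(c(1, 3:6), 1:5), sites = 1:3),
    uncovered = list(qry = c(5000, 15000, 25000, 35000),
                     pairs = cbind(3:6, 1:4), sites = 1:2),
    stop("unknown case: ", which))
  bg <- background_case()
  ref2 <- mk_map(2, 1e4 * (1:6))
  qry2 <- mk_map(2, cfg$qry)
  list(ref_maps = list("1" = bg$ref, "2" = ref2),
       qry_maps = list("1" = bg$qry, "2" = qry2),
       alignments = list(bg$aln, mk_aln(2, qry2, ref2, cfg$pairs)),
       case_sites = cfg$sites)
}

case_site_scores <- function(which) {
  cs <- scoring_case(which)
  res <- assess_maps(cs$ref_maps, cs$qry_maps, cs$alignments)
  sc <- res$site_scores
  sc$score[sc$ref_map_id == 2][cs$case_sites]
}

# random valid restriction maps (positions on a 0.1 bp grid so the CMAP
# one-decimal formatting round-trips exactly)
random_maps <- function(n_maps, max_sites = 8) {
  lapply(seq_len(n_maps), function(i) {
    n <- sample.int(max_sites, 1)
    pos <- round(sort(sample.int(1e6, n)) + sample(0:9, n, TRUE) / 10, 1)
    len <- max(pos) + sample.int(1e4, 1)
    mk_map(i, pos, length_bp = len, coverage = sample(0:50, n, TRUE))
  })
}

random_alignments <- function(n) {
  lapply(seq_len(n), function(i) {
    k <- sample(2:6, 1)
    ref_ids <- sort(sample.int(20, k))
    qry_ids <- if (runif(1) < 0.5) seq_len(k) else rev(seq_len(k))
    map_alignment(i, sample.int(50, 1), sample.int(50, 1),
                  qry_start = 100, qry_end = 90000,
                  ref_start = 100, ref_end = 95000,
                  orientation = sample(c("+", "-"), 1),
                  confidence = round(runif(1, 0, 60), 2),
                  pairs = data.frame(ref_site_id = ref_ids,
                                     qry_site_id = qry_ids))
  })
}
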