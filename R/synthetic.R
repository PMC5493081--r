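# Fully synthetic test data: random genomes with a controlled label density,
# injected misassemblies, noisy query consensus maps cut from the true
# genome, and truth alignments standing in for the external aligner. All
# generators are deterministic under a fixed seed.

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove every occurrence of the motif (both strands) from a sequence by
# flipping the middle base; iterated because a replacement can, rarely,
# create a new occurrence at the junction.
scrub_motifs <- function(sequence, enzyme, max_pass = 10L) {
  swap <- c(A = "C", C = "A", G = "T", T = "G", N = "A")
  for (pass in seq_len(max_pass)) {
    hits <- find_motif_starts(sequence, enzyme)
    if (!length(hits)) return(sequence)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    mid <- hits + nchar(enzyme$recognition) %/% 2L
    chars[mid] <- swap[chars[mid]]
    sequence <- paste0(chars, collapse = "")
  }
  sequence
}

# starts of motif occurrences on either strand (forward coordinates)
find_motif_starts <- function(sequence, enzyme) {
  subject <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enzyme$recognition)
  sort(unique(c(
    Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = TRUE)),
    Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(pat), subject, fixed = TRUE)))))
}

#' Simulate a genome with a controlled restriction-site density
#'
#' A uniform random background is first scrubbed of chance motif occurrences
#' (for a 7-mer those would otherwise contribute roughly one site per 8 kb
#' and swamp the target), then recognition motifs are planted on random
#' strands at exponential spacings tuned to `target_density_per_100kb` —
#' the Poisson spacing model for enzyme sites along a genome.
#'
#' @param length_bp genome length (>= 10 kb).
#' @param enzyme an [enzyme_spec()].
#' @param target_density_per_100kb expected label density; default 11, the
#'   typical Nt.BspQI density of the plant and bacterial genomes this kind
#'   of assessment is run on.
#' @param seed optional integer seed (`NULL` = use the current RNG state).
#' @return a DNA sequence (character scalar).
#' @export
simulate_genome <- function(length_bp, enzyme = get_enzyme("Nt.BspQI"),
                            target_density_per_100kb = 11, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length_bp < 1e4) stop("genome length must be at least 10 kb")
  if (target_density_per_100kb <= 0) stop("density must be > 0")
  motif_len <- nchar(enzyme$recognition)
  spacing <- 1e5 / target_density_per_100kb
  if (spacing < motif_len)
    stop("density ", target_density_per_100kb,
         "/100kb implies spacing shorter than the recognition motif")
  sequence <- scrub_motifs(random_dna(length_bp), enzyme)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  motif_f <- strsplit(enzyme$recognition, "", fixed = TRUE)[[1]]
  motif_r <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(enzyme$recognition))), "", fixed = TRUE)[[1]]
  # plant at gaps = motif length + Exp(spacing - motif length): expected
  # spacing matches the target without overlapping plants
  pos <- 1 + stats::rexp(1, rate = 1 / spacing)
  lo <- enzyme$nick_offset + 2L  # keep both strands' labels inside [1, L]
  hi <- length_bp - motif_len - enzyme$nick_offset
  while (pos <= hi) {
    p <- round(pos)
    if (p >= lo) {
      motif <- if (stats::runif(1) < 0.5) motif_f else motif_r
      chars[p:(p + motif_len - 1L)] <- motif
    }
    pos <- pos + motif_len + stats::rexp(1, rate = 1 / (spacing - motif_len))
  }
  paste0(chars, collapse = "")
}

#' Inject misassemblies into a sequence
#'
#' Corrupts a genome into a mis-assembled "reference": deletions remove a
#' span, insertions add label-free random sequence, misplacements excise a
#' span and reinsert it at a distant position. Events must not overlap.
#' Inserted sequence is motif-scrubbed so an insertion manifests downstream
#' purely as a distance conflict, not as extra labels.
#'
#' @param sequence the true genome (character scalar).
#' @param events data.frame with columns `kind`
#'   (`deletion`/`insertion`/`misplacement`), `start_bp`, `size_bp` and, for
#'   misplacements, `dest_bp` (insertion point of the excised block), all in
#'   coordinates of `sequence`.
#' @param enzyme enzyme whose motif is kept out of inserted sequence.
#' @param seed optional integer seed.
#' @return list with `sequence` (the corrupted assembly), `events`
#'   (realized coordinates on the corrupted sequence: `id`, `kind`,
#'   `start_bp`, `end_bp`, `size_bp`) and `coord_map` (data.frame `g_start`,
#'   `g_end`, `a_start`: piecewise mapping from true-genome to assembly
#'   coordinates; see [map_genome_to_assembly()]).
#' @export
inject_misassemblies <- function(sequence, events = NULL,
                                 enzyme = get_enzyme("Nt.BspQI"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(sequence)
  if (is.null(events) || nrow(events) == 0L) {
    return(list(sequence = sequence,
                events = data.frame(id = integer(), kind = character(),
                                    start_bp = numeric(), end_bp = numeric(),
                                    size_bp = numeric()),
                coord_map = data.frame(g_start = 1, g_end = L, a_start = 1)))
  }
  events <- as.data.frame(events)
  events$id <- seq_len(nrow(events))
  if (any(events$size_bp <= 0)) stop("event size_bp must be > 0")
  spans <- data.frame(
    start = events$start_bp,
    end = ifelse(events$kind == "insertion", events$start_bp - 1,
                 events$start_bp + events$size_bp - 1))
  if (any(spans$start < 1) || any(spans$end > L))
    stop("events must fit inside the sequence")
  ord <- order(spans$start)
  if (nrow(events) > 1L &&
      any(spans$start[ord][-1] <= spans$end[ord][-nrow(events)]))
    stop("requested events overlap")
  if (any(events$kind == "misplacement")) {
    d <- events$dest_bp[events$kind == "misplacement"]
    if (any(is.na(d))) stop("misplacement events need dest_bp")
    for (dd in d)
      if (any(dd >= spans$start & dd <= spans$end))
        stop("misplacement dest_bp must lie outside every event span")
  }

  # partition [1, L] at event breakpoints into reference segments
  breaks <- sort(unique(c(1, events$start_bp,
                          spans$end + 1,
                          events$dest_bp[events$kind == "misplacement"],
                          L + 1)))
  breaks <- breaks[breaks >= 1 & breaks <= L + 1]
  seg <- data.frame(g_start = breaks[-length(breaks)],
                    g_end = breaks[-1] - 1)
  seg$key <- seg$g_start

  # assembly plan: ordered list of pieces, each a ref segment or an insert
  plan <- lapply(seq_len(nrow(seg)), function(i)
    list(type = "ref", g_start = seg$g_start[i], g_end = seg$g_end[i]))
  seg_at <- function(plan, g_pos, field = "g_start") {
    idx <- which(vapply(plan, function(p)
      p$type == "ref" && p[[field]] == g_pos, NA))
    if (length(idx) != 1L) stop("internal error: segment lookup failed")
    idx
  }
  for (e in seq_len(nrow(events))) {
    kind <- events$kind[e]
    s <- events$start_bp[e]; sz <- events$size_bp[e]
    if (kind == "deletion") {
      i1 <- seg_at(plan, s)
      i2 <- seg_at(plan, s + sz - 1, "g_end")
      for (i in i1:i2) plan[[i]]$deleted_by <- events$id[e]
    } else if (kind == "insertion") {
      at <- if (s <= L) seg_at(plan, s) else length(plan) + 1L
      piece <- list(type = "ins", seq = scrub_motifs(random_dna(sz), enzyme),
                    event_id = events$id[e])
      plan <- append(plan, list(piece), after = at - 1L)
    } else if (kind == "misplacement") {
      i1 <- seg_at(plan, s)
      i2 <- seg_at(plan, s + sz - 1, "g_end")
      block <- plan[i1:i2]
      for (b in seq_along(block)) block[[b]]$moved_by <- events$id[e]
      plan <- plan[-(i1:i2)]
      at <- seg_at(plan, events$dest_bp[e])
      plan <- append(plan, block, after = at - 1L)
    } else stop("unknown event kind: ", kind)
  }

  # assemble and record realized coordinates
  pieces <- character()
  coord <- list(); realized <- list()
  a_pos <- 1
  moved_span <- list(); deleted_at <- list()
  for (p in plan) {
    if (p$type == "ref") {
      width <- p$g_end - p$g_start + 1
      if (!is.null(p$deleted_by)) {
        deleted_at[[as.character(p$deleted_by)]] <-
          c(deleted_at[[as.character(p$deleted_by)]], a_pos)
        next
      }
      pieces <- c(pieces, substr(sequence, p$g_start, p$g_end))
      coord[[length(coord) + 1L]] <-
        data.frame(g_start = p$g_start, g_end = p$g_end, a_start = a_pos)
      if (!is.null(p$moved_by)) {
        key <- as.character(p$moved_by)
        moved_span[[key]] <- range(c(moved_span[[key]], a_pos,
                                     a_pos + width - 1))
      }
      a_pos <- a_pos + width
    } else {
      width <- nchar(p$seq)
      pieces <- c(pieces, p$seq)
      realized[[length(realized) + 1L]] <-
        data.frame(id = p$event_id, kind = "insertion", start_bp = a_pos,
                   end_bp = a_pos + width - 1, size_bp = width)
      a_pos <- a_pos + width
    }
  }
  for (e in seq_len(nrow(events))) {
    key <- as.character(events$id[e])
    if (events$kind[e] == "deletion") {
      at <- deleted_at[[key]][1]
      realized[[length(realized) + 1L]] <-
        data.frame(id = events$id[e], kind = "deletion",
                   start_bp = max(1, at - 1), end_bp = min(a_pos - 1, at),
                   size_bp = events$size_bp[e])
    } else if (events$kind[e] == "misplacement") {
      sp <- moved_span[[key]]
      realized[[length(realized) + 1L]] <-
        data.frame(id = events$id[e], kind = "misplacement",
                   start_bp = sp[1], end_bp = sp[2],
                   size_bp = events$size_bp[e])
    }
  }
  realized <- do.call(rbind, realized)
  realized <- realized[order(realized$id), , drop = FALSE]
  rownames(realized) <- NULL
  list(sequence = paste0(pieces, collapse = ""),
       events = realized,
       coord_map = do.call(rbind, coord))
}

#' Map true-genome positions onto the corrupted assembly
#'
#' @param coord_map the `coord_map` from [inject_misassemblies()].
#' @param positions numeric vector of positions on the true genome.
#' @return numeric vector of assembly positions; `NA` for positions falling
#'   in deleted spans.
#' @export
map_genome_to_assembly <- function(coord_map, positions) {
  out <- rep(NA_real_, length(positions))
  for (i in seq_len(nrow(coord_map))) {
    hit <- positions >= coord_map$g_start[i] & positions <= coord_map$g_end[i]
    out[hit] <- coord_map$a_start[i] + positions[hit] - coord_map$g_start[i]
  }
  out
}

#' Simulate noisy query consensus maps from a reference map
#'
#' Cuts the map into overlapping fragments (50% tiling, emulating consensus
#' maps assembled from molecules), perturbs every inter-site interval
#' multiplicatively with Gaussian sizing noise, drops sites i.i.d. (missed
#' labels), sprinkles false labels as a Poisson process, and optionally
#' reverses fragments. Per-site coverage is filled from the tiling depth so
#' the downstream coverage-based reliability heuristic is exercisable.
#'
#' @param ref_map the [restriction_map()] to fragment (typically the digest
#'   of the true genome).
#' @param sizing_sd_fraction fractional SD of the multiplicative interval
#'   noise (0.02 = 2% sizing error, typical of consensus optical maps).
#' @param site_dropout_prob per-site probability of a missed label.
#' @param false_label_rate false labels per bp (e.g. 1e-6).
#' @param fragment_length_bp fragment length (default 150 kb, the scale of
#'   real consensus maps).
#' @param reverse_prob probability a fragment is stored reverse-oriented.
#' @param seed optional integer seed.
#' @return list with `qry_maps` (named list of `restriction_map`),
#'   `correspondence` (data.frame `qry_map_id`, `qry_site_id`,
#'   `ref_site_id`, `reversed`: every surviving true site) and `fragments`
#'   (data.frame `qry_map_id`, `ref_start_bp`, `ref_end_bp`, `reversed`).
#' @export
simulate_query_maps <- function(ref_map, sizing_sd_fraction = 0.02,
                                site_dropout_prob = 0, false_label_rate = 0,
                                fragment_length_bp = 150000,
                                reverse_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(site_dropout_prob >= 0, site_dropout_prob <= 1,
            sizing_sd_fraction >= 0, false_label_rate >= 0,
            reverse_prob >= 0, reverse_prob <= 1)
  sites <- ref_map$sites
  if (nrow(sites) >= 2L) {
    mean_gap <- mean(diff(sites$position_bp))
    if (fragment_length_bp < 10 * mean_gap)
      warning("fragment_length_bp < 10x mean inter-site spacing; ",
              "fragments will carry very few sites")
  }
  step <- max(1, floor(fragment_length_bp / 2))
  starts <- seq(1, max(1, ref_map$length_bp - 1), by = step)
  depth_at <- function(p) sum(starts <= p & p <= starts + fragment_length_bp - 1)
  qry_maps <- list(); corr <- list(); frags <- list()
  next_id <- 0L
  for (s in starts) {
    w_end <- min(s + fragment_length_bp - 1, ref_map$length_bp)
    in_win <- which(sites$position_bp >= s & sites$position_bp <= w_end)
    if (!length(in_win)) next
    keep <- stats::runif(length(in_win)) >= site_dropout_prob
    surv <- in_win[keep]
    if (!length(surv)) next
    off <- sites$position_bp[surv] - s + 1
    if (length(off) > 1L) {
      gaps <- diff(off)
      fac <- pmax(stats::rnorm(length(gaps), 1, sizing_sd_fraction), 0.01)
      off <- off[1] + c(0, cumsum(gaps * fac))
    }
    win_len <- w_end - s + 1
    n_false <- stats::rpois(1, false_label_rate * win_len)
    fpos <- if (n_false > 0) stats::runif(n_false, 1, win_len) else numeric()
    pos <- c(off, fpos)
    truth <- c(sites$site_id[surv], rep(NA_integer_, n_false))
    cov <- c(vapply(sites$position_bp[surv], depth_at, 0),
             rep(1, n_false))
    frag_len <- max(win_len, ceiling(max(pos)) + 1)
    reversed <- stats::runif(1) < reverse_prob
    if (reversed) pos <- frag_len - pos + 1
    ord <- order(pos)
    pos <- round(pos[ord], 1)
    truth <- truth[ord]; cov <- cov[ord]
    dup <- duplicated(pos)
    pos <- pos[!dup]; truth <- truth[!dup]; cov <- cov[!dup]
    next_id <- next_id + 1L
    qry_maps[[as.character(next_id)]] <- restriction_map(
      next_id, frag_len,
      sites_from_positions(pos, coverage = cov, occurrence = cov))
    matched <- which(!is.na(truth))
    if (length(matched))
      corr[[length(corr) + 1L]] <- data.frame(
        qry_map_id = next_id, qry_site_id = matched,
        ref_site_id = truth[matched], reversed = reversed)
    frags[[length(frags) + 1L]] <- data.frame(
      qry_map_id = next_id, ref_start_bp = s, ref_end_bp = w_end,
      reversed = reversed)
  }
  list(qry_maps = qry_maps,
       correspondence = do.call(rbind, corr),
       fragments = do.call(rbind, frags))
}

# longest run-preserving subsequence: indices of the longest strictly
# increasing (or decreasing) subsequence of x; O(n^2), n is small here
longest_monotone_subseq <- function(x, decreasing = FALSE) {
  if (decreasing) x <- -x
  n <- length(x)
  if (n <= 1L) return(seq_len(n))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in 2:n) for (j in 1:(i - 1L))
    if (x[j] < x[i] && len[j] + 1L > len[i]) {
      len[i] <- len[j] + 1L; prev[i] <- j
    }
  i <- which.max(len)
  out <- integer()
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Build truth alignments from a simulation correspondence
#'
#' Stands in for the external aligner: one alignment per query fragment
#' whose pairs are the true site correspondences. Pairs are ordered by
#' reference site id; where a misplacement makes the correspondence
#' non-monotone, the longest monotone run is kept (a real aligner would
#' likewise split there). Confidence is a large constant (50) so truth is
#' never lost to confidence filtering.
#'
#' @param correspondence data.frame `qry_map_id`, `qry_site_id`,
#'   `ref_site_id` (NA allowed: site absent from the reference), optional
#'   logical `reversed`.
#' @param ref_map the reference [restriction_map()] the ids refer to.
#' @param qry_maps named list of query maps.
#' @param confidence confidence assigned to every truth alignment.
#' @return list of [map_alignment()].
#' @export
build_truth_xmap <- function(correspondence, ref_map, qry_maps,
                             confidence = 50) {
  if (is.null(correspondence$reversed)) correspondence$reversed <- FALSE
  out <- list()
  entry <- 0L
  for (qid in unique(correspondence$qry_map_id)) {
    rows <- correspondence[correspondence$qry_map_id == qid &
                             !is.na(correspondence$ref_site_id), , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("query map ", qid, " has no matchable sites; skipped")
      next
    }
    rows <- rows[order(rows$ref_site_id), , drop = FALSE]
    reversed <- rows$reversed[1]
    keep <- longest_monotone_subseq(rows$qry_site_id, decreasing = reversed)
    rows <- rows[keep, , drop = FALSE]
    qm <- qry_maps[[as.character(qid)]]
    ref_pos <- ref_map$sites$position_bp[match(rows$ref_site_id,
                                               ref_map$sites$site_id)]
    qry_pos <- qm$sites$position_bp[match(rows$qry_site_id,
                                          qm$sites$site_id)]
    entry <- entry + 1L
    out[[length(out) + 1L]] <- map_alignment(
      entry_id = entry, qry_map_id = qid, ref_map_id = ref_map$map_id,
      qry_start = qry_pos[1], qry_end = qry_pos[length(qry_pos)],
      ref_start = min(ref_pos), ref_end = max(ref_pos),
      orientation = if (reversed) "-" else "+",
      confidence = confidence,
      pairs = data.frame(ref_site_id = rows$ref_site_id,
                         qry_site_id = rows$qry_site_id))
  }
  out
}

#' Simulate a complete assessment dataset
#'
#' End-to-end generator: simulate a true genome, corrupt it into the
#' assembly under test, digest both, cut noisy query maps from the true
#' genome's map, and build truth alignments of those query maps onto the
#' assembly's map (true-genome site ids are translated through the
#' corruption coordinate map; sites deleted from the assembly become
#' unmatched query sites, exactly as a real aligner would leave them).
#'
#' @param genome_length_bp true genome length (default 1 Mb).
#' @param density_per_100kb label density (default 11).
#' @param events event specification for [inject_misassemblies()] (`NULL`
#'   for a clean assembly).
#' @param enzyme an [enzyme_spec()].
#' @param sizing_sd_fraction,site_dropout_prob,false_label_rate,fragment_length_bp,reverse_prob
#'   noise model, see [simulate_query_maps()].
#' @param contig_name name of the single simulated contig.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return list: `genome`, `assembly` (sequences), `ref_maps`, `key`
#'   (assembly digest), `qry_maps`, `alignments`, `truth` (realized events
#'   with `ref_name`), `coord_map`, `correspondence`.
#' @export
simulate_dataset <- function(genome_length_bp = 1e6, density_per_100kb = 11,
                             events = NULL,
                             enzyme = get_enzyme("Nt.BspQI"),
                             sizing_sd_fraction = 0.02,
                             site_dropout_prob = 0, false_label_rate = 0,
                             fragment_length_bp = 150000, reverse_prob = 0,
                             contig_name = "contig_1", seed = 1) {
  set.seed(seed)
  genome <- simulate_genome(genome_length_bp, enzyme, density_per_100kb)
  corrupt <- inject_misassemblies(genome, events, enzyme)
  assembly <- stats::setNames(corrupt$sequence, contig_name)
  digest <- digest_fasta(assembly, enzyme)
  ref_map <- digest$maps[[1]]
  genome_map <- digest_fasta(stats::setNames(genome, contig_name),
                             enzyme)$maps[[1]]
  sim <- simulate_query_maps(genome_map, sizing_sd_fraction,
                             site_dropout_prob, false_label_rate,
                             fragment_length_bp, reverse_prob)
  corr <- sim$correspondence
  # translate true-genome site ids to assembly site ids
  g_pos <- genome_map$sites$position_bp[match(corr$ref_site_id,
                                              genome_map$sites$site_id)]
  a_pos <- map_genome_to_assembly(corrupt$coord_map, g_pos)
  corr$ref_site_id <- ref_map$sites$site_id[match(round(a_pos, 1),
                                                  round(ref_map$sites$position_bp, 1))]
  alignments <- build_truth_xmap(corr, ref_map, sim$qry_maps)
  truth <- corrupt$events
  if (nrow(truth)) truth$ref_name <- contig_name
  list(genome = genome, assembly = assembly, ref_maps = digest$maps,
       key = digest$key, genome_map = genome_map, qry_maps = sim$qry_maps,
       alignments = alignments, truth = truth,
       coord_map = corrupt$coord_map, correspondence = corr)
}
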