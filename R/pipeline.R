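# The assessment pipeline: wire confidence filtering, diff computation,
# global fences, classification, scoring, indel calls, regions and the
# normality check into one run over a set of maps and alignments.

#' Assess an assembly's restriction maps against query optical maps
#'
#' Runs the full assessment: alignments below the confidence threshold are
#' dropped; distance diffs of all matched adjacent site pairs are pooled
#' across every alignment and contig to place the global Tukey fences; each
#' interval is classified; every reference site receives a 0-4 quality
#' score with a reliability flag; outlier intervals yield indel calls;
#' questionable regions are assembled for export.
#'
#' @param ref_maps named list of reference [restriction_map()]s (in-silico
#'   digest of the assembly).
#' @param qry_maps named list of query [restriction_map()]s (BioNano
#'   consensus maps).
#' @param alignments list of [map_alignment()] (from an XMAP).
#' @param confidence_threshold minimum alignment confidence (default 10).
#' @param key_table optional data.frame `name`, `cmap_id` naming the contigs.
#' @return object of class `omapqc_assessment`: list with `intervals`
#'   (classified diffs), `fences`, `site_scores`, `indels`, `regions`,
#'   `case_counts`, `normality` (`NULL` when fewer than 8 diffs),
#'   `n_alignments` (pre/post filter), `confidence_threshold`, `key_table`.
#' @export
assess_maps <- function(ref_maps, qry_maps, alignments,
                        confidence_threshold = 10, key_table = NULL) {
  n_before <- length(alignments)
  alignments <- filter_alignments_by_confidence(alignments,
                                                confidence_threshold)
  if (!length(alignments))
    stop("no alignments at or above confidence ", confidence_threshold)
  iv <- do.call(rbind, lapply(alignments, function(a) {
    rm_ <- ref_maps[[as.character(a$ref_map_id)]]
    qm <- qry_maps[[as.character(a$qry_map_id)]]
    if (is.null(rm_)) stop("reference map ", a$ref_map_id, " not supplied")
    if (is.null(qm)) stop("query map ", a$qry_map_id, " not supplied")
    compute_interval_diffs(a, rm_, qm)
  }))
  if (is.null(iv) || nrow(iv) < 4L)
    stop("insufficient data: ", if (is.null(iv)) 0L else nrow(iv),
         " matched-pair intervals after filtering (need >= 4); ",
         "lower the confidence threshold or supply more alignments")
  fences <- tukey_fences(iv$diff)
  iv$class <- classify_intervals(iv, fences)
  site_scores <- do.call(rbind, lapply(ref_maps, function(rm_)
    score_reference_sites(rm_, alignments, qry_maps, fences)))
  rownames(site_scores) <- NULL
  site_scores <- reliability_flags(site_scores,
                                   mean_coverage = mean(site_scores$coverage),
                                   confidence_threshold = confidence_threshold)
  structure(list(
    intervals = iv,
    fences = fences,
    site_scores = site_scores,
    indels = call_indels(iv, fences),
    regions = build_regions(site_scores, iv, key_table),
    case_counts = summarize_cases(site_scores),
    normality = if (nrow(iv) >= 8L) diff_normality(iv$diff, fences) else NULL,
    n_alignments = c(before_filter = n_before,
                     after_filter = length(alignments)),
    confidence_threshold = confidence_threshold,
    key_table = key_table), class = "omapqc_assessment")
}

#' @export
print.omapqc_assessment <- function(x, ...) {
  cat("optical-map assembly assessment\n")
  cat(sprintf("  alignments: %d read, %d at confidence >= %.1f\n",
              x$n_alignments["before_filter"], x$n_alignments["after_filter"],
              x$confidence_threshold))
  cat(sprintf("  intervals: %d; ", nrow(x$intervals)))
  print(x$fences)
  cls <- table(factor(x$intervals$class, levels = interval_classes))
  cat("  interval classes: ",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat("  site scores (4..0): ",
      paste(sprintf("%s=%d", names(x$case_counts), x$case_counts),
            collapse = ", "), "\n")
  cat(sprintf("  indel calls: %d; questionable regions: %d\n",
              nrow(x$indels), nrow(x$regions)))
  if (!is.null(x$normality)) { cat("  "); print(x$normality) }
  invisible(x)
}

#' Digest an assembly FASTA to CMAP (command-line workflow step)
#'
#' Writes `<out_prefix>.cmap` and the contig-name key table
#' `<out_prefix>.key`.
#'
#' @param fasta_path input assembly FASTA.
#' @param enzyme_name a built-in enzyme name (see [builtin_enzymes()]).
#' @param min_separation label-merge distance in bp (default 0).
#' @param out_prefix output path prefix.
#' @return invisibly, the list from [digest_fasta()].
#' @export
run_digest <- function(fasta_path, enzyme_name = "Nt.BspQI",
                       min_separation = 0, out_prefix = "digest") {
  enzyme <- get_enzyme(enzyme_name)
  seqs <- read_fasta(fasta_path)
  digest <- digest_fasta(seqs, enzyme, min_separation)
  write_cmap(digest$maps, paste0(out_prefix, ".cmap"))
  write_key_table(digest$key, paste0(out_prefix, ".key"))
  invisible(digest)
}

#' Assess previously aligned maps (command-line workflow step)
#'
#' The previously-aligned-data workflow: reads the reference CMAP (in-silico
#' digest of the assembly), the query CMAP (BioNano consensus maps) and the
#' XMAP produced by an external aligner, runs [assess_maps()], and writes
#' `site_scores.tsv`, `regions.tsv`, `regions.gff3`, `case_counts.tsv`,
#' `indels.tsv`, `normality.txt` and `assess.log` into `out_dir`.
#'
#' @param r_cmap,q_cmap,xmap input file paths.
#' @param key_table optional path to the contig-name key table.
#' @param confidence_threshold minimum alignment confidence (default 10).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the `omapqc_assessment`.
#' @export
run_assess <- function(r_cmap, q_cmap, xmap, key_table = NULL,
                       confidence_threshold = 10, out_dir = ".") {
  ref_maps <- read_cmap(r_cmap)
  qry_maps <- read_cmap(q_cmap)
  alignments <- read_xmap(xmap)
  key <- if (!is.null(key_table)) read_key_table(key_table) else NULL
  res <- assess_maps(ref_maps, qry_maps, alignments, confidence_threshold,
                     key)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)
  tsv <- function(d, f) utils::write.table(d, out(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(res$site_scores, "site_scores.tsv")
  tsv(res$regions, "regions.tsv")
  tsv(res$indels, "indels.tsv")
  tsv(data.frame(score = names(res$case_counts),
                 n_sites = res$case_counts), "case_counts.tsv")
  lengths <- vapply(ref_maps, `[[`, 0, "length_bp")
  names(lengths) <- vapply(ref_maps, function(m) {
    if (!is.null(key)) {
      nm <- key$name[match(m$map_id, key$cmap_id)]
      if (!is.na(nm)) return(nm)
    }
    as.character(m$map_id)
  }, "")
  regions_to_gff3(res$regions, out("regions.gff3"), lengths)
  log_lines <- utils::capture.output(print(res))
  if (!is.null(res$normality))
    writeLines(utils::capture.output(print(res$normality)),
               out("normality.txt"))
  writeLines(log_lines, out("assess.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(res)
}

# parse a flat key=value simulation config file
parse_sim_config <- function(path) {
  known <- c("genome_length_bp", "density_per_100kb", "enzyme",
             "sizing_sd_fraction", "site_dropout_prob", "false_label_rate",
             "fragment_length_bp", "reverse_prob", "events")
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% known)
      stop("unknown config key '", key, "'; known keys: ",
           paste(known, collapse = ", "))
    cfg[[key]] <- trimws(kv[2])
  }
  for (k in setdiff(known, c("enzyme", "events")))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!is.null(cfg$events)) cfg$events <- parse_event_spec(cfg$events)
  cfg
}

# events as "kind:start:size[:dest]" separated by ';'
parse_event_spec <- function(text) {
  if (!nzchar(text)) return(NULL)
  toks <- strsplit(strsplit(text, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  do.call(rbind, lapply(toks, function(t) {
    if (length(t) < 3L) stop("malformed event spec: ", paste(t, collapse = ":"))
    data.frame(kind = t[1], start_bp = as.numeric(t[2]),
               size_bp = as.numeric(t[3]),
               dest_bp = if (length(t) >= 4L) as.numeric(t[4]) else NA_real_)
  }))
}

#' Simulate a complete dataset to disk (command-line workflow step)
#'
#' Writes `assembly.fasta`, `r.cmap` (assembly digest), `assembly.key`,
#' `q.cmap` (noisy query maps), `truth.xmap`, `truth_events.tsv` and a copy
#' of the effective configuration into `out_dir`; the file set feeds
#' [run_assess()] unchanged.
#'
#' @param config `NULL`, a named list, or a path to a flat `key=value`
#'   config file (keys: `genome_length_bp`, `density_per_100kb`, `enzyme`,
#'   `sizing_sd_fraction`, `site_dropout_prob`, `false_label_rate`,
#'   `fragment_length_bp`, `reverse_prob`, `events` as
#'   `kind:start:size[:dest];...`).
#' @param seed integer seed; the file set is byte-deterministic given it.
#' @param out_dir output directory.
#' @return invisibly, the list from [simulate_dataset()].
#' @export
run_simulate <- function(config = NULL, seed = 1, out_dir = ".") {
  if (is.character(config)) config <- parse_sim_config(config)
  if (is.null(config)) config <- list()
  enzyme <- get_enzyme(if (is.null(config$enzyme)) "Nt.BspQI"
                       else config$enzyme)
  args <- list(
    genome_length_bp = config$genome_length_bp %||% 1e6,
    density_per_100kb = config$density_per_100kb %||% 11,
    events = config$events,
    enzyme = enzyme,
    sizing_sd_fraction = config$sizing_sd_fraction %||% 0.02,
    site_dropout_prob = config$site_dropout_prob %||% 0,
    false_label_rate = config$false_label_rate %||% 0,
    fragment_length_bp = config$fragment_length_bp %||% 150000,
    reverse_prob = config$reverse_prob %||% 0,
    seed = seed)
  ds <- do.call(simulate_dataset, args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)
  write_fasta(ds$assembly, out("assembly.fasta"))
  write_cmap(ds$ref_maps, out("r.cmap"))
  write_key_table(ds$key, out("assembly.key"))
  write_cmap(ds$qry_maps, out("q.cmap"))
  qlen <- stats::setNames(vapply(ds$qry_maps, `[[`, 0, "length_bp"),
                          names(ds$qry_maps))
  rlen <- stats::setNames(vapply(ds$ref_maps, `[[`, 0, "length_bp"),
                          names(ds$ref_maps))
  write_xmap(ds$alignments, out("truth.xmap"), qlen, rlen)
  utils::write.table(ds$truth, out("truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_out <- c(sprintf("seed=%d", seed),
               sprintf("enzyme=%s", enzyme$name),
               sprintf("%s=%s",
                       c("genome_length_bp", "density_per_100kb",
                         "sizing_sd_fraction", "site_dropout_prob",
                         "false_label_rate", "fragment_length_bp",
                         "reverse_prob"),
                       c(args$genome_length_bp, args$density_per_100kb,
                         args$sizing_sd_fraction, args$site_dropout_prob,
                         args$false_label_rate, args$fragment_length_bp,
                         args$reverse_prob)))
  writeLines(cfg_out, out("config.txt"))
  invisible(ds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
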