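# Reporting: per-score case counts, GFF3 export of questionable regions,
# and the score/coverage series behind the double-y diagnostic plot.

# GFF3 column-3 terms for each region category. Descriptive strings rather
# than Sequence Ontology accessions: SO has no term matching a restriction
# site-count conflict, so the whole set stays symmetric and self-describing.
gff3_types <- c(MISSING_IN_REF = "missing_in_reference",
                EXTRA_IN_REF = "extra_in_reference",
                SITE_COUNT_CONFLICT = "site_count_conflict",
                COMPLEX = "complex_conflict",
                UNMAPPED = "unmapped_region")

#' Count reference sites per quality score
#'
#' @param site_scores stacked data.frame from [score_reference_sites()].
#' @return named integer vector, scores `"4"` down to `"0"`; sums to the
#'   total number of reference sites.
#' @export
summarize_cases <- function(site_scores) {
  counts <- table(factor(site_scores$score, levels = 4:0))
  stats::setNames(as.integer(counts), names(counts))
}

#' Write questionable regions as GFF3
#'
#' One feature per region; column 3 carries the category (see the mapping
#' in the package's methods vignette), the score column the minimum site
#' score inside the region, and the attributes the region id and mean diff.
#' Coordinates are 1-based inclusive, as throughout the package, so they
#' pass into GFF3 unchanged.
#'
#' @param regions data.frame from [build_regions()].
#' @param path output path.
#' @param contig_lengths optional named numeric vector (names = contig
#'   names); when given, `##sequence-region` directives are written and
#'   out-of-bounds regions raise an error.
#' @return `path`, invisibly.
#' @export
regions_to_gff3 <- function(regions, path, contig_lengths = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(contig_lengths))
    lines <- c(lines, sprintf("##sequence-region %s 1 %.0f",
                              names(contig_lengths), contig_lengths))
  if (nrow(regions)) {
    if (!is.null(contig_lengths)) {
      len <- contig_lengths[regions$ref_name]
      bad <- which(is.na(len) | regions$start_bp < 1 | regions$end_bp > len)
      if (length(bad))
        stop("region ", bad[1], " (", regions$ref_name[bad[1]], ":",
             regions$start_bp[bad[1]], "-", regions$end_bp[bad[1]],
             ") lies outside its contig")
    }
    type <- gff3_types[regions$category]
    if (anyNA(type))
      stop("unknown region category: ",
           regions$category[which(is.na(type))[1]])
    score <- ifelse(is.na(regions$min_score_in_region), ".",
                    as.character(regions$min_score_in_region))
    mean_diff <- ifelse(is.na(regions$mean_diff_bp), "NA",
                        sprintf("%.1f", regions$mean_diff_bp))
    attrs <- sprintf("ID=region_%d;category=%s;mean_diff=%s",
                     seq_len(nrow(regions)), regions$category, mean_diff)
    lines <- c(lines, sprintf("%s\tomapqc\t%s\t%.0f\t%.0f\t%s\t.\t.\t%s",
                              regions$ref_name, type, regions$start_bp,
                              regions$end_bp, score, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Score/coverage series for the double-y diagnostic plot
#'
#' One row per reference site of a contig, sorted by position: the 0-4
#' quality score next to the query-map coverage supporting the site. Plotted
#' with coverage on the left axis and score on the right, low-score sites
#' with high coverage stand out as well-supported misassembly calls, while
#' low-score low-coverage sites may simply lack optical-map data.
#'
#' @param site_scores stacked data.frame from [score_reference_sites()].
#' @param ref_map the [restriction_map()] of the contig to extract.
#' @param path optional path; when given the table is also written as
#'   tab-separated text.
#' @return data.frame `position_bp`, `score`, `coverage`.
#' @export
plot_series <- function(site_scores, ref_map, path = NULL) {
  rows <- site_scores[site_scores$ref_map_id == ref_map$map_id, , drop = FALSE]
  if (!nrow(rows))
    stop("no scores available for map ", ref_map$map_id)
  rows <- rows[order(rows$position_bp),
               c("position_bp", "score", "coverage")]
  rownames(rows) <- NULL
  if (!is.null(path))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rows
}

#' Double-y plot of coverage and quality score along a contig
#'
#' @param series data.frame from [plot_series()].
#' @param title plot title.
#' @return a ggplot object (requires ggplot2).
#' @export
plot_score_coverage <- function(series, title = "site quality vs coverage") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  max_cov <- max(series$coverage, 1)
  ggplot2::ggplot(series, ggplot2::aes(x = position_bp)) +
    ggplot2::geom_col(ggplot2::aes(y = coverage), width = 1,
                      colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(y = score * max_cov / 4),
                        colour = "firebrick", size = 0.8) +
    ggplot2::scale_y_continuous(
      name = "query-map coverage",
      sec.axis = ggplot2::sec_axis(~ . * 4 / max_cov,
                                   name = "quality score (0-4)")) +
    ggplot2::labs(x = "reference position (bp)", title = title) +
    ggplot2::theme_minimal()
}
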