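#' Construct a restriction map
#'
#' A restriction map is one contig's ordered set of labelled nicking-enzyme
#' sites, as carried in a BioNano CMAP: an integer map id, the contig length
#' in bp, and one row per site with its 1-based position and the per-site
#' coverage statistics reported by the map assembler (all zero for maps
#' produced by in-silico digestion).
#'
#' @param map_id positive integer map identifier (the `CMapId`).
#' @param length_bp contig length in bp (positive).
#' @param sites data.frame with columns `site_id`, `position_bp`, `coverage`,
#'   `occurrence`, `std_dev`. Positions must be strictly increasing within
#'   `(0, length_bp]` and `site_id` must run 1..N in position order.
#' @return an object of class `restriction_map`.
#' @export
restriction_map <- function(map_id, length_bp, sites) {
  map_id <- as.integer(map_id)
  stopifnot(length(map_id) == 1L, map_id >= 1L,
            length(length_bp) == 1L, length_bp > 0)
  needed <- c("site_id", "position_bp", "coverage", "occurrence", "std_dev")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols))
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  sites <- as.data.frame(sites)[, needed]
  n <- nrow(sites)
  if (n > 0L) {
    if (any(diff(sites$position_bp) <= 0))
      stop("site positions must be strictly increasing (map ", map_id, ")")
    if (any(sites$position_bp <= 0) || any(sites$position_bp > length_bp))
      stop("site positions must lie in (0, length_bp] (map ", map_id, ")")
    if (!identical(as.integer(sites$site_id), seq_len(n)))
      stop("site_id must be 1..N consecutive in position order (map ",
           map_id, ")")
    if (any(sites$coverage < sites$occurrence) || any(sites$occurrence < 0))
      stop("each site needs coverage >= occurrence >= 0 (map ", map_id, ")")
  }
  structure(list(map_id = map_id, length_bp = as.numeric(length_bp),
                 sites = sites),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat(sprintf("restriction_map %d: %.0f bp, %d sites\n",
              x$map_id, x$length_bp, nrow(x$sites)))
  invisible(x)
}

# empty site table with the right column types
empty_sites <- function() {
  data.frame(site_id = integer(), position_bp = numeric(),
             coverage = numeric(), occurrence = numeric(),
             std_dev = numeric())
}

# build a site table from positions, in-silico defaults for the stats
sites_from_positions <- function(positions, coverage = 0, occurrence = 0,
                                 std_dev = 0) {
  n <- length(positions)
  data.frame(site_id = seq_len(n), position_bp = as.numeric(positions),
             coverage = rep_len(as.numeric(coverage), n),
             occurrence = rep_len(as.numeric(occurrence), n),
             std_dev = rep_len(as.numeric(std_dev), n))
}

#' Construct a map-to-map alignment
#'
#' One query-map-to-reference-map alignment as carried in one XMAP row:
#' aligned coordinates on both maps, orientation, the aligner's confidence
#' score, and the ordered list of matched (reference site id, query site id)
#' pairs.
#'
#' @param entry_id,qry_map_id,ref_map_id positive integers.
#' @param qry_start,qry_end,ref_start,ref_end aligned coordinates in bp.
#' @param orientation `"+"` or `"-"`. For `"-"` the query map aligns
#'   reverse-complemented, so its matched site ids decrease while the
#'   reference ids increase.
#' @param confidence non-negative alignment confidence score.
#' @param pairs data.frame with integer columns `ref_site_id`, `qry_site_id`;
#'   `ref_site_id` must be strictly increasing.
#' @return an object of class `map_alignment`.
#' @export
map_alignment <- function(entry_id, qry_map_id, ref_map_id,
                          qry_start, qry_end, ref_start, ref_end,
                          orientation, confidence, pairs) {
  if (!orientation %in% c("+", "-"))
    stop("orientation must be '+' or '-', got: ", orientation)
  if (is.na(confidence) || confidence < 0)
    stop("confidence must be >= 0")
  pairs <- as.data.frame(pairs)
  if (!all(c("ref_site_id", "qry_site_id") %in% names(pairs)))
    stop("pairs needs columns ref_site_id, qry_site_id")
  pairs$ref_site_id <- as.integer(pairs$ref_site_id)
  pairs$qry_site_id <- as.integer(pairs$qry_site_id)
  if (nrow(pairs) > 1L && any(diff(pairs$ref_site_id) <= 0))
    stop("ref_site_id in pairs must be strictly increasing (entry ",
         entry_id, ")")
  structure(list(entry_id = as.integer(entry_id),
                 qry_map_id = as.integer(qry_map_id),
                 ref_map_id = as.integer(ref_map_id),
                 qry_start = as.numeric(qry_start),
                 qry_end = as.numeric(qry_end),
                 ref_start = as.numeric(ref_start),
                 ref_end = as.numeric(ref_end),
                 orientation = orientation,
                 confidence = as.numeric(confidence),
                 pairs = pairs[, c("ref_site_id", "qry_site_id")]),
            class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf(
    "map_alignment %d: qry %d -> ref %d (%s), conf %.1f, %d matched pairs\n",
    x$entry_id, x$qry_map_id, x$ref_map_id, x$orientation, x$confidence,
    nrow(x$pairs)))
  invisible(x)
}
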