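# Readers/writers for the BioNano text formats (CMAP v0.1, XMAP) and FASTA.
# The vendor formats are tab-separated with '#' header lines and a '#h'
# column-name line; positions are printed with one decimal place.

cmap_columns <- c("CMapId", "ContigLength", "NumSites", "SiteID",
                  "LabelChannel", "Position", "StdDev", "Coverage",
                  "Occurrence")

xmap_columns <- c("XmapEntryID", "QryContigID", "RefContigID", "QryStartPos",
                  "QryEndPos", "RefStartPos", "RefEndPos", "Orientation",
                  "Confidence", "HitEnum", "QryLen", "RefLen", "LabelChannel",
                  "Alignment")

# Split the data section of a BioNano table file into a data.frame using the
# '#h' line for column names; extra columns beyond `expected` are dropped
# with a warning (vendor versions add columns over time).
read_bionano_table <- function(path, expected) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  header_idx <- grep("^#h\\s", lines)
  cols <- if (length(header_idx)) {
    strsplit(sub("^#h\\s+", "", lines[header_idx[1]]), "\t")[[1]]
  } else {
    expected
  }
  cols <- trimws(cols)
  extra <- setdiff(cols, expected)
  if (length(extra))
    warning("ignoring unrecognised columns: ", paste(extra, collapse = ", "))
  missing_cols <- setdiff(expected, cols)
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  data_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(data_idx)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(expected)))
    names(out) <- expected
    return(out)
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(cols))
  if (length(bad))
    stop("malformed row at line ", data_idx[bad[1]], " of ", path,
         ": expected ", length(cols), " fields, found ",
         lengths(fields)[bad[1]])
  mat <- do.call(rbind, fields)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- cols
  out <- out[, expected, drop = FALSE]
  attr(out, "line_numbers") <- data_idx
  out
}

as_numeric_checked <- function(x, column, lines, path) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !is.na(x))
  if (length(bad))
    stop("malformed value '", x[bad[1]], "' in column ", column, " at line ",
         lines[bad[1]], " of ", path)
  y
}

#' Read a BioNano CMAP file
#'
#' Parses a CMAP v0.1 file into a set of [restriction_map()] objects, one per
#' `CMapId`. The `LabelChannel` 0 terminal row of each map (the map-end
#' sentinel) is excluded from the site list but checked against the declared
#' contig length.
#'
#' @param path path to a `.cmap` file.
#' @return named list of `restriction_map`, names = map ids.
#' @export
read_cmap <- function(path) {
  tab <- read_bionano_table(path, cmap_columns)
  lines <- attr(tab, "line_numbers")
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  for (col in cmap_columns)
    tab[[col]] <- as_numeric_checked(tab[[col]], col, lines, path)
  maps <- list()
  for (id in unique(tab$CMapId)) {
    rows <- tab[tab$CMapId == id, , drop = FALSE]
    len <- rows$ContigLength[1]
    sentinel <- rows[rows$LabelChannel == 0, , drop = FALSE]
    if (nrow(sentinel) && abs(sentinel$Position[1] - len) > 0.5)
      stop("map ", id, ": end-sentinel position ", sentinel$Position[1],
           " disagrees with ContigLength ", len)
    body <- rows[rows$LabelChannel != 0, , drop = FALSE]
    body <- body[order(body$SiteID), , drop = FALSE]
    if (nrow(body) && any(diff(body$Position) <= 0))
      stop("map ", id, ": site positions are not strictly increasing")
    sites <- data.frame(site_id = as.integer(body$SiteID),
                        position_bp = body$Position,
                        coverage = body$Coverage,
                        occurrence = body$Occurrence,
                        std_dev = body$StdDev)
    maps[[as.character(as.integer(id))]] <-
      restriction_map(id, len, sites)
  }
  maps
}

#' Write a BioNano CMAP file
#'
#' Emits CMAP v0.1, including the `LabelChannel` 0 end-sentinel row each map
#' ends with. `read_cmap(write_cmap(x))` is the identity up to the one-decimal
#' numeric formatting of the format.
#'
#' @param maps list of [restriction_map()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(maps, path) {
  header <- c("# CMAP File Version:\t0.1",
              "# Label Channels:\t1",
              "# Nickase Recognition Site 1:\tunknown",
              sprintf("# Number of Consensus Nanomaps:\t%d", length(maps)),
              paste0("#h ", paste(cmap_columns, collapse = "\t")),
              paste0("#f ", paste(c("int", "float", "int", "int", "int",
                                    "float", "float", "float", "float"),
                                  collapse = "\t")))
  rows <- character()
  for (m in maps) {
    s <- m$sites
    n <- nrow(s)
    fmt <- function(cmap_id, len, num, sid, ch, pos, sd, cov, occ) {
      sprintf("%d\t%.1f\t%d\t%d\t%d\t%.1f\t%.1f\t%.1f\t%.1f",
              cmap_id, len, num, sid, ch, pos, sd, cov, occ)
    }
    if (n > 0L)
      rows <- c(rows, fmt(m$map_id, m$length_bp, n, s$site_id, 1L,
                          s$position_bp, s$std_dev, s$coverage,
                          s$occurrence))
    # end sentinel
    rows <- c(rows, fmt(m$map_id, m$length_bp, n, n + 1L, 0L, m$length_bp,
                        0, 1, 1))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Parse a BioNano alignment-pair string
#'
#' The XMAP `Alignment` column lists matched sites as `"(r,q)(r,q)..."` with
#' `r` a reference site id and `q` a query site id.
#'
#' @param text the alignment string; `""` yields zero pairs.
#' @return data.frame with integer columns `ref_site_id`, `qry_site_id`.
#' @export
parse_alignment_pairs <- function(text) {
  empty <- data.frame(ref_site_id = integer(), qry_site_id = integer())
  if (is.na(text) || !nzchar(text)) return(empty)
  ml <- gregexpr("\\((\\d+),(\\d+)\\)", text)
  m <- ml[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(text))
    stop("malformed alignment-pair string: ", text)
  toks <- regmatches(text, ml)[[1]]
  nums <- regmatches(toks, gregexpr("\\d+", toks))
  data.frame(ref_site_id = as.integer(vapply(nums, `[`, "", 1L)),
             qry_site_id = as.integer(vapply(nums, `[`, "", 2L)))
}

format_alignment_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return("")
  paste0(sprintf("(%d,%d)", pairs$ref_site_id, pairs$qry_site_id),
         collapse = "")
}

#' Read a BioNano XMAP file
#'
#' @param path path to an `.xmap` file.
#' @return list of [map_alignment()] objects in file order.
#' @export
read_xmap <- function(path) {
  tab <- read_bionano_table(path, xmap_columns)
  lines <- attr(tab, "line_numbers")
  if (nrow(tab) == 0L) return(list())
  num_cols <- setdiff(xmap_columns, c("Orientation", "HitEnum", "Alignment"))
  for (col in num_cols)
    tab[[col]] <- as_numeric_checked(tab[[col]], col, lines, path)
  bad_orient <- which(!tab$Orientation %in% c("+", "-"))
  if (length(bad_orient))
    stop("unknown orientation token '", tab$Orientation[bad_orient[1]],
         "' at line ", lines[bad_orient[1]], " of ", path)
  lapply(seq_len(nrow(tab)), function(i) {
    map_alignment(entry_id = tab$XmapEntryID[i],
                  qry_map_id = tab$QryContigID[i],
                  ref_map_id = tab$RefContigID[i],
                  qry_start = tab$QryStartPos[i], qry_end = tab$QryEndPos[i],
                  ref_start = tab$RefStartPos[i], ref_end = tab$RefEndPos[i],
                  orientation = tab$Orientation[i],
                  confidence = tab$Confidence[i],
                  pairs = parse_alignment_pairs(tab$Alignment[i]))
  })
}

#' Write a BioNano XMAP file
#'
#' @param alignments list of [map_alignment()] objects.
#' @param path output path.
#' @param qry_lengths,ref_lengths optional named numeric vectors (names = map
#'   ids) used to fill the `QryLen`/`RefLen` columns; 0 when unknown.
#' @return `path`, invisibly.
#' @export
write_xmap <- function(alignments, path, qry_lengths = NULL,
                       ref_lengths = NULL) {
  header <- c("# XMAP File Version:\t0.2",
              "# Label Channels:\t1",
              paste0("#h ", paste(xmap_columns, collapse = "\t")))
  len_of <- function(tbl, id) {
    v <- tbl[[as.character(id)]]
    if (is.null(v)) 0 else v
  }
  rows <- vapply(alignments, function(a) {
    n <- nrow(a$pairs)
    hit <- if (n > 0L) paste0(n, "M") else "0M"
    sprintf("%d\t%d\t%d\t%.1f\t%.1f\t%.1f\t%.1f\t%s\t%.2f\t%s\t%.1f\t%.1f\t%d\t%s",
            a$entry_id, a$qry_map_id, a$ref_map_id,
            a$qry_start, a$qry_end, a$ref_start, a$ref_end,
            a$orientation, a$confidence, hit,
            len_of(as.list(qry_lengths), a$qry_map_id),
            len_of(as.list(ref_lengths), a$ref_map_id),
            1L, format_alignment_pairs(a$pairs))
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Filter alignments on the aligner confidence score
#'
#' The confidence score is the aligner's per-alignment quality; entries below
#' the user threshold are excluded from assessment. The cut is inclusive:
#' `confidence >= threshold` is kept. The default of 10 sits at the bottom of
#' the commonly recommended 10-20 band.
#'
#' @param alignments list of [map_alignment()].
#' @param threshold non-negative confidence cutoff (default 10).
#' @return the retained alignments, input order preserved.
#' @export
filter_alignments_by_confidence <- function(alignments, threshold = 10) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("confidence threshold must be a single non-negative number")
  keep <- vapply(alignments, function(a) a$confidence >= threshold, NA)
  alignments[keep]
}

#' Read a FASTA file
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return named character vector of uppercase sequences; names are the
#'   headers truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  seqs
}

#' Write a FASTA file
#'
#' @param sequences named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read/write the contig-name key table
#'
#' CMAP identifies maps only by integer ids; the key table records the
#' contig-name-to-id mapping written beside any CMAP generated by digestion.
#'
#' @param path path to a two-column tab-separated file `name<TAB>cmap_id`.
#' @return data.frame with columns `name` (character), `cmap_id` (integer).
#' @export
read_key_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = c("character", "integer"))
  if (!identical(names(tab), c("name", "cmap_id")))
    stop("key table must have columns name, cmap_id: ", path)
  tab
}

#' @rdname read_key_table
#' @param key data.frame with columns `name`, `cmap_id`.
#' @export
write_key_table <- function(key, path) {
  utils::write.table(key[, c("name", "cmap_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
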