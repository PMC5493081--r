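# In-silico digestion of an assembly into a restriction map using a
# nicking-enzyme motif. Nt.BspQI (GCTCTTCN) nicks one strand one base past
# its 7 bp recognition sequence; the labelled position on the map is the
# nick, i.e. recognition start + 7 on the forward strand.

#' Define a nicking enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition sequence, ACGT only.
#' @param nick_offset bases downstream of the recognition start (forward
#'   strand) at which the labelled nick sits; `>= 0`.
#' @return an object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, recognition, nick_offset) {
  recognition <- toupper(recognition)
  if (grepl("[^ACGT]", recognition))
    stop("recognition sequence must contain only ACGT: ", recognition)
  if (length(nick_offset) != 1L || nick_offset < 0)
    stop("nick_offset must be >= 0")
  structure(list(name = name, recognition = recognition,
                 nick_offset = as.integer(nick_offset)),
            class = "enzyme_spec")
}

#' Built-in nicking enzymes
#'
#' Currently the single-enzyme BioNano workhorse Nt.BspQI (GCTCTTCN: the
#' label is placed at the nick one base past the 7 bp recognition site).
#'
#' @return named list of [enzyme_spec()].
#' @export
builtin_enzymes <- function() {
  list("Nt.BspQI" = enzyme_spec("Nt.BspQI", "GCTCTTC", 7L))
}

#' Look up a built-in enzyme by name
#'
#' @param name enzyme name as listed by [builtin_enzymes()].
#' @return an [enzyme_spec()].
#' @export
get_enzyme <- function(name) {
  enz <- builtin_enzymes()
  if (!name %in% names(enz))
    stop("unknown enzyme '", name, "'; built-ins: ",
         paste(names(enz), collapse = ", "))
  enz[[name]]
}

#' Locate nicking-enzyme label positions on a sequence
#'
#' Scans both strands for the recognition motif. A forward occurrence
#' starting at `s` labels position `s + nick_offset`; a reverse-strand
#' occurrence (the reverse complement of the motif on the forward sequence)
#' ending at `e` labels `e - nick_offset`. Occurrences containing an N never
#' match; labels falling outside `[1, length]` (motifs at the extreme
#' termini) are dropped and tallied in the `n_dropped` attribute. Duplicate
#' labels from the two strands are collapsed.
#'
#' @param sequence DNA sequence (character scalar, ACGTN).
#' @param enzyme an [enzyme_spec()].
#' @return strictly sorted numeric vector of 1-based label positions, with
#'   attribute `n_dropped` counting out-of-range labels.
#' @export
find_nick_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  subject <- Biostrings::DNAString(toupper(sequence))
  pat <- Biostrings::DNAString(enzyme$recognition)
  fwd <- Biostrings::matchPattern(pat, subject, fixed = TRUE)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                  subject, fixed = TRUE)
  labels <- c(Biostrings::start(fwd) + enzyme$nick_offset,
              Biostrings::end(rev) - enzyme$nick_offset)
  in_range <- labels >= 1 & labels <= length(subject)
  out <- sort(unique(labels[in_range]))
  attr(out, "n_dropped") <- sum(!in_range)
  out
}

# merge label positions closer than min_separation into cluster midpoints
merge_close_sites <- function(positions, min_separation) {
  if (min_separation <= 0 || length(positions) < 2L) return(positions)
  cluster <- cumsum(c(1, diff(positions) >= min_separation))
  as.numeric(tapply(positions, cluster,
                    function(p) (min(p) + max(p)) / 2))
}

#' Digest a FASTA assembly into restriction maps
#'
#' One [restriction_map()] per sequence, map ids assigned in file order
#' starting at 1. Labels closer than `min_separation` are merged to their
#' cluster midpoint (off by default; the knob models the limited resolution
#' of real optical maps). Coverage statistics are 0: this is an in-silico
#' map.
#'
#' @param sequences named character vector (e.g. from [read_fasta()]).
#' @param enzyme an [enzyme_spec()]; default Nt.BspQI.
#' @param min_separation minimum label separation in bp (default 0 = no
#'   merging).
#' @return list with `maps` (named list of `restriction_map`) and `key`
#'   (data.frame `name`, `cmap_id`).
#' @export
digest_fasta <- function(sequences, enzyme = get_enzyme("Nt.BspQI"),
                         min_separation = 0) {
  if (length(sequences) == 0L)
    stop("no sequences to digest")
  if (min_separation < 0) stop("min_separation must be >= 0")
  maps <- list()
  for (i in seq_along(sequences)) {
    pos <- find_nick_sites(sequences[[i]], enzyme)
    pos <- merge_close_sites(as.numeric(pos), min_separation)
    maps[[as.character(i)]] <-
      restriction_map(i, nchar(sequences[[i]]), sites_from_positions(pos))
  }
  key <- data.frame(name = names(sequences), cmap_id = seq_along(sequences))
  list(maps = maps, key = key)
}
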