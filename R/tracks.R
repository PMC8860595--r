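# Per-library 3' end tracks.  A track is a sparse map (chrom, strand, pos)
# -> value held as a keyed data.table; positions absent from the map read as
# zero.  Raw tracks carry non-negative integer counts, normalized tracks
# non-negative reals; the two states are distinguished by the `normalized`
# attribute.

#' Construct a 3' end track
#'
#' @param df data.frame/data.table with columns `chrom`, `strand`, `pos`
#'   (0-based nucleotide position of a transcript 3' end), `value` (>= 0).
#'   Duplicate positions are summed.
#' @param library_id Library identifier.
#' @param normalized Logical; `FALSE` for raw counts.
#' @return An `end_track` object.
#' @export
end_track <- function(df = NULL, library_id = "lib", normalized = FALSE) {
  if (is.null(df) || nrow(df) == 0) {
    dt <- data.table::data.table(chrom = character(0), strand = character(0),
                                 pos = integer(0), value = numeric(0))
  } else {
    dt <- data.table::as.data.table(df)[, list(chrom, strand,
                                               pos = as.integer(pos),
                                               value = as.numeric(value))]
    if (any(dt$value < 0)) stop("track values must be non-negative")
    if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    dt <- dt[, list(value = sum(value)), by = list(chrom, strand, pos)]
    dt <- dt[value > 0]
  }
  data.table::setkey(dt, chrom, strand, pos)
  structure(list(counts = dt, library_id = library_id,
                 normalized = normalized),
            class = "end_track")
}

#' @export
print.end_track <- function(x, ...) {
  cat("<end_track>", x$library_id,
      if (x$normalized) "(normalized)" else "(raw)",
      "-", nrow(x$counts), "positions, total signal",
      format(sum(x$counts$value)), "\n")
  invisible(x)
}

#' Total signal of a track
#' @param track An `end_track`.
#' @return Numeric scalar.
#' @export
track_total <- function(track) sum(track$counts$value)

#' Read a strand's bedGraph file into a 3' end track
#'
#' Intervals must be sorted and non-overlapping; runs are expanded to
#' per-nucleotide values (bedGraph coordinates are already 0-based
#' half-open).  An empty file yields an all-zero track.
#'
#' @param path bedGraph file for a single strand.
#' @param strand `"+"` or `"-"`.
#' @param library_id Library identifier recorded on the track.
#' @param normalized Logical flag recorded on the track.
#' @return An `end_track` covering one strand.
#' @export
read_endtrack <- function(path, strand, library_id = basename(path),
                          normalized = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  info <- file.info(path)
  if (info$size == 0)
    return(end_track(NULL, library_id, normalized))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) return(end_track(NULL, library_id, normalized))
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(S4Vectors::mcols(gr)$score))
  if (any(dt$value < 0)) stop("negative value in bedGraph: ", path)
  data.table::setorder(dt, chrom, start)
  ov <- dt[, any(start[-1] < end[-.N]), by = chrom]$V1
  if (any(ov, na.rm = TRUE)) stop("overlapping intervals in bedGraph: ", path)
  wid <- dt$end - dt$start
  expanded <- data.table::data.table(
    chrom = rep(dt$chrom, wid),
    strand = strand,
    pos = unlist(lapply(seq_len(nrow(dt)),
                        function(i) seq.int(dt$start[i], dt$end[i] - 1L))),
    value = rep(dt$value, wid))
  end_track(expanded, library_id, normalized)
}

#' Write a 3' end track as per-strand bedGraph files
#'
#' Emits the canonical form: sorted, with consecutive equal-valued positions
#' merged into runs.  One file per strand using the suffixes
#' `.plus.bedgraph` and `.minus.bedgraph`; files are written even when a
#' strand is empty, so `read_endtrack_pair()` round-trips.
#'
#' @param track An `end_track`.
#' @param prefix Output path prefix.
#' @return Named character vector of the two written paths, invisibly.
#' @export
write_endtrack <- function(track, prefix) {
  stopifnot(inherits(track, "end_track"))
  paths <- c("+" = paste0(prefix, ".plus.bedgraph"),
             "-" = paste0(prefix, ".minus.bedgraph"))
  for (st in c("+", "-")) {
    dt <- track$counts[strand == st][order(chrom, pos)]
    if (nrow(dt) == 0) {
      file.create(paths[[st]])
      next
    }
    # merge consecutive positions with equal value into runs
    brk <- c(TRUE, dt$chrom[-1] != dt$chrom[-nrow(dt)] |
                   dt$pos[-1] != dt$pos[-nrow(dt)] + 1L |
                   dt$value[-1] != dt$value[-nrow(dt)])
    run <- cumsum(brk)
    runs <- dt[, list(chrom = chrom[1], start = pos[1],
                      end = pos[.N] + 1L, value = value[1]), by = run]
    out <- data.frame(runs$chrom, runs$start, runs$end,
                      format(runs$value, scientific = FALSE, trim = TRUE))
    utils::write.table(out, paths[[st]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read both strand files of a library
#'
#' @param prefix Path prefix used by [write_endtrack()].
#' @inheritParams read_endtrack
#' @return An `end_track` with both strands.
#' @export
read_endtrack_pair <- function(prefix, library_id = basename(prefix),
                               normalized = FALSE) {
  plus <- read_endtrack(paste0(prefix, ".plus.bedgraph"), "+",
                        library_id, normalized)
  minus <- read_endtrack(paste0(prefix, ".minus.bedgraph"), "-",
                         library_id, normalized)
  end_track(rbind(plus$counts, minus$counts), library_id, normalized)
}

#' Pool 3' end signal across libraries
#'
#' @param tracks List of `end_track` objects sharing chromosome naming.
#' @return A keyed data.table `(chrom, strand, pos, value)` of summed signal.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) > 0)
  dt <- data.table::rbindlist(lapply(tracks, function(t) t$counts))
  dt <- dt[, list(value = sum(value)), by = list(chrom, strand, pos)]
  data.table::setkey(dt, chrom, strand, pos)
  dt
}

# Sum per-position signal of one track within strand-matched intervals.
# intervals: data.frame(chrom, start, end, strand); returns numeric vector
# aligned with intervals rows.
sum_in_intervals <- function(track, intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) return(numeric(0))
  dt <- if (inherits(track, "end_track")) track$counts else track
  iv <- data.table::as.data.table(intervals)[, list(
    chrom, strand, istart = as.integer(start), iend = as.integer(end))]
  if (nrow(dt) == 0) return(rep(0, nrow(intervals)))
  res <- dt[iv, on = c("chrom", "strand", "pos>=istart", "pos<iend"),
            sum(value), by = .EACHI]
  out <- res$V1
  out[is.na(out)] <- 0
  out
}
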