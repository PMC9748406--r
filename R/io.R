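#' Ternary per-bin heterozygosity sequence
#'
#' The HMM's observation track: one symbol per non-overlapping bin
#' (default 100 bp) along a diploid genome, each bin homozygous (`0`),
#' heterozygous (`1`) or missing (`.`).
#'
#' @param codes Integer codes (0 = HOM, 1 = HET, 2 = MISSING), a character
#'   vector / single string over `0`, `1`, `.`, or a factor.
#' @param name Sequence identifier.
#' @param bin_size Bases per bin (>= 1); metadata, not encoded in files.
#' @return A `ternary_sequence` object.
#' @examples
#' ternary_sequence("0101.", name = "chr1")
#' @export
ternary_sequence <- function(codes, name = "seq", bin_size = 100L) {
  codes <- obs_codes(codes)
  if (length(codes) == 0L) stop("`codes` must be nonempty", call. = FALSE)
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L)
    stop("`bin_size` must be >= 1", call. = FALSE)
  structure(list(codes = codes, name = as.character(name),
                 bin_size = bin_size),
            class = "ternary_sequence")
}

#' @export
length.ternary_sequence <- function(x) length(unclass(x)$codes)

#' @export
print.ternary_sequence <- function(x, ...) {
  d <- unclass(x)
  tab <- tabulate(d$codes + 1L, 3L)
  cat(sprintf("<ternary_sequence> %s: %d bins of %d bp (HOM %d, HET %d, missing %d)\n",
              d$name, length(d$codes), d$bin_size, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
as.character.ternary_sequence <- function(x, dialect = c("ternary", "psmcfa"), ...) {
  dialect <- match.arg(dialect)
  map <- if (dialect == "ternary") c("0", "1", ".") else c("T", "K", "N")
  paste(map[unclass(x)$codes + 1L], collapse = "")
}

PSMCFA_MAP <- c(T = 0L, K = 1L, N = 2L)
TERNARY_MAP <- c("0" = 0L, "1" = 1L, "." = 2L)

#' Read psmcfa-format observation sequences
#'
#' Parses a FASTA-like file with one symbol per bin. Two dialects are
#' accepted, per record but not mixed within one: the psmcfa alphabet
#' `T` (homozygous) / `K` (heterozygous) / `N` (missing), case-insensitive,
#' and the ternary alphabet `0` / `1` / `.`.
#'
#' @param path File path (or connection) to read.
#' @param bin_size Bases per bin to attach to each sequence (metadata).
#' @return A list of [ternary_sequence()] objects, one per FASTA record.
#' @export
read_psmcfa <- function(path, bin_size = 100L) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (length(headers) == 0L)
    stop("no FASTA records found in ", path, call. = FALSE)
  if (headers[1] != 1L && any(nzchar(trimws(lines[seq_len(headers[1] - 1L)]))))
    stop("content before first FASTA header in ", path, call. = FALSE)
  starts <- headers + 1L
  ends <- c(headers[-1] - 1L, length(lines))
  out <- vector("list", length(headers))
  for (r in seq_along(headers)) {
    name <- sub("^>\\s*", "", lines[headers[r]])
    name <- sub("\\s.*$", "", name)
    body_idx <- seq(starts[r], length.out = max(0L, ends[r] - starts[r] + 1L))
    body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
    if (length(body_idx) == 0L)
      stop(sprintf("empty record '%s' at line %d", name, headers[r]),
           call. = FALSE)
    chars <- toupper(unlist(strsplit(trimws(lines[body_idx]), "")))
    in_psmcfa <- chars %in% names(PSMCFA_MAP)
    in_ternary <- chars %in% names(TERNARY_MAP)
    bad <- !(in_psmcfa | in_ternary)
    if (any(bad)) {
      # report the line containing the first offending symbol
      cum <- cumsum(nchar(trimws(lines[body_idx])))
      off_line <- body_idx[which(cum >= which(bad)[1])[1]]
      stop(sprintf("unknown symbol '%s' in record '%s' at line %d",
                   chars[bad][1], name, off_line), call. = FALSE)
    }
    if (any(in_psmcfa) && any(in_ternary))
      stop(sprintf("record '%s' mixes psmcfa (T/K/N) and ternary (0/1/.) symbols",
                   name), call. = FALSE)
    codes <- if (all(in_psmcfa)) unname(PSMCFA_MAP[chars])
             else unname(TERNARY_MAP[chars])
    out[[r]] <- ternary_sequence(codes, name = name, bin_size = bin_size)
  }
  out
}

#' Write observation sequences in psmcfa format
#'
#' @param seqs A [ternary_sequence()] or list of them.
#' @param path Output file path (or connection).
#' @param dialect `"psmcfa"` (`T`/`K`/`N`) or `"ternary"` (`0`/`1`/`.`).
#' @param width Symbols per line (default 60).
#' @return `path`, invisibly.
#' @export
write_psmcfa <- function(seqs, path, dialect = c("psmcfa", "ternary"),
                         width = 60L) {
  dialect <- match.arg(dialect)
  if (inherits(seqs, "ternary_sequence")) seqs <- list(seqs)
  map <- if (dialect == "psmcfa") c("T", "K", "N") else c("0", "1", ".")
  lines <- character(0)
  for (s in seqs) {
    stopifnot(inherits(s, "ternary_sequence"))
    d <- unclass(s)
    chars <- map[d$codes + 1L]
    n <- length(chars)
    rows <- split(chars, (seq_len(n) - 1L) %/% width)
    lines <- c(lines, paste0(">", d$name),
               vapply(rows, paste, character(1), collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}
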