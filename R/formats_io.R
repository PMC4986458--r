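#' Decode one mpileup base-call string into ACGT counts
#'
#' Resolves the samtools mpileup base-call syntax for a single sample at a
#' single site: `.` and `,` stand for the reference base, `ACGTacgt` for
#' explicit calls, `^X` (read start plus mapping quality) and `$` (read end)
#' carry no base, and `+<n><seq>`/`-<n><seq>` insertions/deletions are
#' consumed without contributing counts. Placeholder (`*`), reference-skip
#' (`<`, `>`) and ambiguous (`N`) marks are dropped, so the reported depth is
#' the number of unambiguous A/C/G/T calls.
#'
#' @param bases character scalar, the base-call column.
#' @param ref reference base (single character, case-insensitive).
#' @return named integer vector with elements `A`, `C`, `G`, `T`.
#' @examples
#' decode_pileup_bases(".,T", "A")   # A=2, T=1
#' decode_pileup_bases(".+2AT.", "G") # insertion discarded: G=2
#' @export
decode_pileup_bases <- function(bases, ref) {
  stopifnot(is.character(bases), length(bases) == 1L)
  ref <- toupper(ref)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (is.na(bases) || bases == "" || bases == "*") return(counts)
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                      # caret + mapping-quality char
    } else if (ch == "$" || ch == "*" || ch == "<" || ch == ">" ||
               ch == "N" || ch == "n") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                     # skip the inserted/deleted sequence
    } else {
      b <- if (ch == "." || ch == ",") ref else toupper(ch)
      if (b %in% names(counts)) counts[b] <- counts[b] + 1L
      i <- i + 1L
    }
  }
  counts
}

#' Read a multi-sample mpileup stream into per-site base counts
#'
#' Parses samtools-mpileup text (one `depth bases quals` column block per
#' sample) into a long table of per-sample A/C/G/T counts. Indels, read
#' start/end marks and ambiguity codes are consumed without contributing
#' counts; depth is the sum of the four decoded base counts (see
#' [decode_pileup_bases()]).
#'
#' @param path path to an mpileup text file, or a connection.
#' @param sample_names character vector naming the sample column blocks, in
#'   file order.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `sample`,
#'   `A`, `C`, `G`, `T`, `depth`.
#' @export
read_pileup <- function(path, sample_names) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_samp <- length(sample_names)
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 3L + 2L * n_samp) {
      # tolerate dropped quality column on zero-depth blocks
      f <- .expand_zero_depth(f, n_samp)
    }
    if (length(f) != 3L + 3L * n_samp) {
      stop(sprintf("malformed pileup line %d: expected %d fields, got %d",
                   li, 3L + 3L * n_samp, length(f)))
    }
    ref <- toupper(f[3L])
    cnt <- matrix(0L, nrow = n_samp, ncol = 4L,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    for (s in seq_len(n_samp)) {
      cnt[s, ] <- decode_pileup_bases(f[3L + 3L * (s - 1L) + 2L], ref)
    }
    out[[li]] <- data.frame(
      chrom = f[1L], pos = as.integer(f[2L]), ref = ref,
      sample = sample_names, A = cnt[, "A"], C = cnt[, "C"],
      G = cnt[, "G"], T = cnt[, "T"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$depth <- res$A + res$C + res$G + res$T
  res
}

.expand_zero_depth <- function(f, n_samp) {
  # some writers emit "0 * *" -> fine; others "0 *" -> pad quality column
  out <- f[1:3]
  i <- 4L
  for (s in seq_len(n_samp)) {
    if (i + 2L <= length(f) && !is.na(suppressWarnings(as.integer(f[i])))) {
      out <- c(out, f[i], f[i + 1L], f[i + 2L]); i <- i + 3L
    } else {
      out <- c(out, f[i], f[i + 1L], "*"); i <- i + 2L
    }
  }
  out
}

#' Write per-site per-sample counts as mpileup text
#'
#' Inverse of [read_pileup()] up to base ordering: reference-matching calls
#' are written as `.`, alternates as upper-case letters, and qualities as a
#' run of `I`. Used by the simulator so its output can round-trip through
#' the reader.
#'
#' @param counts data.frame as returned by [read_pileup()].
#' @param path output file path.
#' @param sample_names sample order for the column blocks.
#' @export
write_pileup <- function(counts, path, sample_names) {
  key <- paste(counts$chrom, counts$pos)
  sites <- counts[!duplicated(key), c("chrom", "pos", "ref")]
  sites <- sites[order(sites$chrom, sites$pos), ]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sites))) {
    sub <- counts[counts$chrom == sites$chrom[i] & counts$pos == sites$pos[i], ]
    blocks <- character(length(sample_names))
    for (s in seq_along(sample_names)) {
      row <- sub[sub$sample == sample_names[s], , drop = FALSE]
      if (nrow(row) == 0L) { blocks[s] <- "0\t*\t*"; next }
      calls <- character(0)
      for (b in c("A", "C", "G", "T")) {
        nb <- row[[b]][1L]
        if (nb > 0L) {
          sym <- if (b == sites$ref[i]) "." else b
          calls <- c(calls, rep(sym, nb))
        }
      }
      dp <- length(calls)
      blocks[s] <- if (dp == 0L) "0\t*\t*" else
        paste(dp, paste(calls, collapse = ""),
              strrep("I", dp), sep = "\t")
    }
    writeLines(paste(sites$chrom[i], sites$pos[i], sites$ref[i],
                     paste(blocks, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED3/BED4 file of capture target regions
#'
#' Converts the half-open 0-based BED convention to the package's 1-based
#' closed convention. The central targeted site is the interval midpoint
#' unless a numeric fourth column names a 1-based central position.
#'
#' @param path BED file path or connection.
#' @return data.frame with columns `chrom`, `start`, `end`, `central`
#'   (all 1-based, closed intervals).
#' @export
read_target_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED input needs at least 3 columns")
  start0 <- as.numeric(tab[[2L]]); end0 <- as.numeric(tab[[3L]])
  if (any(end0 <= start0)) {
    stop("BED interval with end <= start at line ",
         which(end0 <= start0)[1L])
  }
  start <- as.integer(start0 + 1L)
  end <- as.integer(end0)
  central <- if (ncol(tab) >= 4L && is.numeric(tab[[4L]])) {
    as.integer(tab[[4L]])
  } else {
    as.integer(floor((start + end) / 2))
  }
  if (any(central < start | central > end)) {
    stop("central site outside its interval")
  }
  data.frame(chrom = as.character(tab[[1L]]), start = start, end = end,
             central = central, stringsAsFactors = FALSE)
}

#' Write target regions back to BED
#'
#' Inverse of [read_target_bed()]: 1-based closed intervals become 0-based
#' half-open records, with the central site as the fourth column.
#'
#' @param targets data.frame as returned by [read_target_bed()].
#' @param path output path.
#' @export
write_target_bed <- function(targets, path) {
  utils::write.table(
    data.frame(targets$chrom, targets$start - 1L, targets$end,
               targets$central),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a taxon-by-site matrix in relaxed PHYLIP format
#'
#' Missing cells (`NA`) are written as `?`. Taxon names must be unique and
#' free of whitespace; relaxed PHYLIP places a single space between name and
#' sequence, so names are not truncated.
#'
#' @param matrix character matrix, rows = taxa (rownames required),
#'   columns = sites; cells are single characters or `NA`.
#' @param path output path.
#' @export
write_phylip_matrix <- function(matrix, path) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("empty matrix cannot be written")
  }
  taxa <- rownames(matrix)
  if (is.null(taxa) || anyDuplicated(taxa) || any(grepl("\\s", taxa))) {
    stop("taxa must have unique, whitespace-free names")
  }
  cells <- matrix
  cells[is.na(cells)] <- "?"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(matrix), ncol(matrix)), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(taxa[i], paste(cells[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a relaxed PHYLIP matrix written by [write_phylip_matrix()]
#'
#' @param path input path.
#' @return character matrix with `NA` at `?` cells.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  ntax <- hdr[1L]; nsite <- hdr[2L]
  mat <- matrix(NA_character_, nrow = ntax, ncol = nsite)
  taxa <- character(ntax)
  for (i in seq_len(ntax)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    taxa[i] <- f[1L]
    seqc <- strsplit(f[2L], "", fixed = TRUE)[[1L]]
    if (length(seqc) != nsite) stop("sequence length mismatch for ", taxa[i])
    seqc[seqc == "?"] <- NA_character_
    mat[i, ] <- seqc
  }
  rownames(mat) <- taxa
  mat
}
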