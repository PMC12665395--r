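#' Superalignments
#'
#' A `superalignment` is a concatenated multiple sequence alignment held as
#' one taxa-by-sites character matrix: unique taxon labels, one sequence per
#' taxon (all of length `L`), an alphabet (`"dna"` or `"protein"`), and an
#' optional partition map recording gene boundaries.  Sequences are stored
#' internally as raw byte vectors (one byte per residue, upper-cased), which
#' keeps multi-megabase alignments compact and makes column extraction cheap.
#'
#' Missing-data semantics: for DNA, `A C G T U` are informative and anything
#' else (gaps `-`, `?`, `N`, IUPAC partial ambiguities `R`, `Y`, ...) counts
#' as missing or ambiguous; for protein, the 20 standard one-letter codes are
#' informative and `X - ? * .` and other codes count as missing.  Ambiguity
#' codes are counted as missing for coverage purposes but are passed through
#' untouched when alignments are written for external engines.
#'
#' @param seqs named character vector of sequences, or a character matrix with
#'   one row per taxon (rownames are labels), or a named list of single
#'   characters strings.
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to auto-detect (at least
#'   90 percent of non-gap residues in `A C G T U N` means DNA).
#' @param partition_map optional data frame with columns `name`, `start`,
#'   `end` (1-based, inclusive) giving non-overlapping gene ranges.
#' @return An object of class `superalignment` with elements `labels`,
#'   `seqs` (named list of raw vectors), `L`, `alphabet`, `partition_map`.
#' @examples
#' aln <- superalignment(c(t1 = "ACGT", t2 = "ACGA", t3 = "ACGC"))
#' aln$L
#' @export
superalignment <- function(seqs, alphabet = NULL, partition_map = NULL) {
  if (is.matrix(seqs)) {
    labs <- rownames(seqs)
    seqs <- apply(seqs, 1L, paste0, collapse = "")
    names(seqs) <- labs
  }
  if (is.list(seqs)) seqs <- unlist(seqs)
  labs <- names(seqs)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("every sequence must carry a non-empty taxon label")
  if (anyDuplicated(labs))
    stop("duplicate taxon labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  raws <- lapply(seqs, function(s) charToRaw(toupper(s)))
  names(raws) <- labs
  lens <- lengths(raws)
  L <- lens[[1L]]
  if (any(lens != L)) {
    bad <- labs[lens != L][1L]
    stop("ragged alignment: taxon '", bad, "' has ", lens[[match(bad, labs)]],
         " residues, expected ", L)
  }
  if (L < 1L) stop("alignment has zero sites")
  if (is.null(alphabet)) alphabet <- detect_alphabet(raws)
  alphabet <- match.arg(alphabet, c("dna", "protein"))
  if (!is.null(partition_map)) partition_map <- validate_partition_map(partition_map, L)
  structure(
    list(labels = labs, seqs = raws, L = as.integer(L),
         alphabet = alphabet, partition_map = partition_map),
    class = "superalignment")
}

INFORMATIVE_DNA <- charToRaw("ACGTU")
INFORMATIVE_AA  <- charToRaw("ACDEFGHIKLMNPQRSTVWY")

informative_bytes <- function(alphabet) {
  if (alphabet == "dna") INFORMATIVE_DNA else INFORMATIVE_AA
}

detect_alphabet <- function(raws) {
  gapish <- charToRaw("-?.")
  dnaish <- charToRaw("ACGTUN")
  res <- unlist(lapply(raws, function(r) r[!(r %in% gapish)]), use.names = FALSE)
  if (length(res) == 0L) return("dna")
  if (mean(res %in% dnaish) >= 0.9) "dna" else "protein"
}

validate_partition_map <- function(pm, L) {
  pm <- as.data.frame(pm)
  stopifnot(all(c("name", "start", "end") %in% names(pm)))
  pm$start <- as.integer(pm$start); pm$end <- as.integer(pm$end)
  if (any(pm$start < 1L) || any(pm$end > L) || any(pm$end < pm$start))
    stop("partition ranges must satisfy 1 <= start <= end <= L")
  o <- order(pm$start)
  if (any(pm$start[o][-1L] <= pm$end[o][-nrow(pm)]))
    stop("partition ranges overlap")
  pm
}

#' @export
print.superalignment <- function(x, ...) {
  cat("superalignment:", length(x$labels), "taxa x", x$L, "sites (",
      x$alphabet, ")\n")
  if (!is.null(x$partition_map))
    cat("  partitions:", nrow(x$partition_map), "\n")
  invisible(x)
}

#' @rdname superalignment
#' @param x a `superalignment`.
#' @export
as.matrix.superalignment <- function(x, ...) {
  m <- do.call(rbind, lapply(x$seqs, function(r) rawToChar(r, multiple = TRUE)))
  rownames(m) <- x$labels
  m
}

# columns of the alignment as a taxa x |sites| raw matrix
aln_columns <- function(aln, sites) {
  m <- matrix(as.raw(0L), nrow = length(aln$labels), ncol = length(sites))
  for (i in seq_along(aln$seqs)) m[i, ] <- aln$seqs[[i]][sites]
  rownames(m) <- aln$labels
  m
}

#' Read a superalignment from FASTA or relaxed PHYLIP
#'
#' FASTA parsing is delegated to [Biostrings::readBStringSet()].  PHYLIP is
#' read in the relaxed sequential dialect (taxon label up to whitespace, then
#' the sequence, possibly wrapped over lines); the strict 10-character dialect
#' is also accepted on read but never written.
#'
#' @param path file path.
#' @param format `"fasta"`, `"phylip"`, or `"auto"` (sniff the first
#'   non-blank character: `>` means FASTA).
#' @param alphabet,partition_map passed to [superalignment()].
#' @return A validated [superalignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                           alphabet = NULL, partition_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    head <- readLines(path, n = 50L, warn = FALSE)
    head <- head[nzchar(trimws(head))]
    format <- if (length(head) && startsWith(trimws(head[1L]), ">"))
      "fasta" else "phylip"
  }
  seqs <- if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    out <- as.character(ss)
    # FASTA headers: label is the first whitespace-delimited token
    names(out) <- vapply(strsplit(names(ss), "[ \t]+"), `[[`, character(1), 1L)
    out
  } else {
    read_phylip(path)
  }
  superalignment(seqs, alphabet = alphabet, partition_map = partition_map)
}

read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header: ", lines[1L])
  ntax <- as.integer(hdr[1L]); nsites <- as.integer(hdr[2L])
  # relaxed sequential: tokenize; a label token is followed by sequence
  # tokens accumulated until nsites residues are seen
  toks <- unlist(strsplit(trimws(lines[-1L]), "[ \t]+"), use.names = FALSE)
  labs <- character(ntax); seqs <- character(ntax)
  i <- 0L; ti <- 1L; ok <- TRUE
  while (i < ntax && ti <= length(toks)) {
    i <- i + 1L
    labs[i] <- toks[ti]; ti <- ti + 1L
    acc <- character(0); got <- 0L
    while (got < nsites && ti <= length(toks)) {
      acc <- c(acc, toks[ti]); got <- got + nchar(toks[ti]); ti <- ti + 1L
    }
    seqs[i] <- paste0(acc, collapse = "")
    if (got != nsites) { ok <- FALSE; break }
  }
  if (!ok || i < ntax || ti <= length(toks)) {
    # fall back to the strict dialect: 10-character name field, one taxon
    # per record, sequence possibly wrapped is not supported strictly here
    body <- lines[-1L]
    if (length(body) != ntax)
      stop("cannot parse PHYLIP: taxon '", labs[max(i, 1L)],
           "' has ", nchar(seqs[max(i, 1L)]), " residues, header declares ",
           nsites)
    labs <- trimws(substr(body, 1L, 10L))
    seqs <- gsub("[ \t]", "", substr(body, 11L, nchar(body)))
  }
  if (any(nchar(seqs) != nsites)) {
    bad <- which(nchar(seqs) != nsites)[1L]
    stop("PHYLIP: taxon '", labs[bad], "' has ", nchar(seqs[bad]),
         " residues, header declares ", nsites)
  }
  names(seqs) <- labs
  seqs
}

#' Write a superalignment to FASTA or relaxed PHYLIP
#'
#' @param aln a [superalignment()].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  chr <- vapply(aln$seqs, rawToChar, character(1))
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(chr)
    names(ss) <- aln$labels
    Biostrings::writeXStringSet(ss, path, width = 80L)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%d %d", length(aln$labels), aln$L), con)
    writeLines(paste(aln$labels, chr), con)
  }
  invisible(path)
}

#' Read a partition map
#'
#' Accepts either a 3-column TSV (`name`, `start`, `end`; 1-based inclusive)
#' or a NEXUS-style block of `charset name = start-end;` lines.
#'
#' @param path file path.
#' @return data frame with columns `name`, `start`, `end`.
#' @export
read_partition_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cs <- grepl("^\\s*charset\\s", lines, ignore.case = TRUE)
  if (any(cs)) {
    m <- regmatches(lines[cs],
      regexec("charset\\s+(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*;",
              lines[cs], ignore.case = TRUE))
    ok <- lengths(m) == 4L
    if (!all(ok)) stop("unparseable charset line: ", lines[cs][!ok][1L])
    return(data.frame(name = vapply(m, `[[`, "", 2L),
                      start = as.integer(vapply(m, `[[`, "", 3L)),
                      end = as.integer(vapply(m, `[[`, "", 4L))))
  }
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("name", "start", "end"),
                    stringsAsFactors = FALSE)
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab
}

#' Per-taxon missing-data profile
#'
#' For each taxon, `mf` is the fraction of sites whose residue is missing,
#' ambiguous, or a gap.  The dataset-level `mf` quoted in reports is the
#' maximum over taxa.
#'
#' @param aln a [superalignment()].
#' @return data frame with columns `taxon` and `mf`.
#' @examples
#' aln <- superalignment(c(a = "ACGT????", b = "ACGTACGT"))
#' coverage_profile(aln)
#' @export
coverage_profile <- function(aln) {
  inf <- informative_bytes(aln$alphabet)
  mf <- vapply(aln$seqs, function(r) mean(!(r %in% inf)), numeric(1))
  data.frame(taxon = aln$labels, mf = unname(mf), stringsAsFactors = FALSE)
}

#' Warn about or drop data-poor taxa
#'
#' Phylogenomic supermatrices sometimes contain taxa with extreme data
#' sparsity; subsamples drawn from such data can contain almost no informative
#' residues for those taxa.  In `warn` mode every taxon whose missing fraction
#' exceeds `warn_threshold` triggers a warning and the alignment is returned
#' unchanged; in `drop` mode taxa at or above `remove_threshold` are removed
#' (and logged in the `removed` attribute), with warnings for the remaining
#' sparse taxa.
#'
#' @param aln a [superalignment()].
#' @param warn_threshold warn above this missing fraction (default 0.5).
#' @param remove_threshold drop at or above this missing fraction in `drop`
#'   mode (default 0.95).
#' @param mode `"warn"` or `"drop"`.
#' @return The (possibly reduced) alignment; attribute `removed` lists dropped
#'   taxa, attribute `sparsity_warnings` the warned ones.
#' @export
enforce_sparsity_policy <- function(aln, warn_threshold = 0.5,
                                    remove_threshold = 0.95,
                                    mode = c("warn", "drop")) {
  mode <- match.arg(mode)
  stopifnot(warn_threshold > 0, warn_threshold <= 1,
            remove_threshold > 0, remove_threshold <= 1)
  prof <- coverage_profile(aln)
  removed <- character(0)
  if (mode == "drop") {
    removed <- prof$taxon[prof$mf >= remove_threshold]
    if (length(removed)) {
      keep <- setdiff(aln$labels, removed)
      if (length(keep) < 4L)
        stop("dropping ", length(removed), " data-poor taxa would leave ",
             length(keep), " < 4 taxa; no meaningful unrooted topology")
      aln <- superalignment(
        vapply(aln$seqs[keep], rawToChar, character(1)),
        alphabet = aln$alphabet, partition_map = aln$partition_map)
      prof <- prof[prof$taxon %in% keep, ]
    }
  }
  warned <- prof$taxon[prof$mf > warn_threshold]
  for (tx in warned)
    warning("taxon '", tx, "' has ",
            sprintf("%.1f%%", 100 * prof$mf[prof$taxon == tx]),
            " missing or ambiguous sites", call. = FALSE)
  attr(aln, "removed") <- removed
  attr(aln, "sparsity_warnings") <- warned
  aln
}
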