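#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP text format: a title line, locus names (either
#' one comma-separated line or one name per line), then population blocks
#' separated by lines reading `Pop` (case-insensitive), each block holding
#' individual lines of the form `name , 0101 0202 ...`.  Both 2-digit and
#' 3-digit allele coding are accepted; `00`/`000` codes a missing allele, and
#' a genotype with either allele missing is treated as missing.
#'
#' @param path path to a GENEPOP file.
#' @param pop_names optional character vector of population labels, one per
#'   `Pop` block, overriding the default labelling.  By default each block is
#'   labelled by the name of its last individual (the GENEPOP convention);
#'   when those names are unusable (empty or duplicated) blocks fall back to
#'   `Pop1..PopK`.
#' @return A [genotype_table].
#' @export
read_genepop <- function(path, pop_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("not a GENEPOP file: fewer than 3 lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("no 'Pop' separator found after the locus list")
  loci <- unlist(strsplit(lines[2:(first_pop - 1L)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names found")
  L <- length(loci)

  blocks <- split(
    which(!is_pop & seq_along(lines) > first_pop & nzchar(trimws(lines))),
    cumsum(is_pop)[!is_pop & seq_along(lines) > first_pop &
                     nzchar(trimws(lines))]
  )
  if (length(blocks) == 0L || length(blocks) != sum(is_pop) ||
      any(lengths(blocks) == 0L))
    stop("empty population block in GENEPOP file")

  nm <- character(0); gts <- list(); popidx <- integer(0); lastnames <- character(0)
  width <- NA_integer_
  for (b in seq_along(blocks)) {
    for (ln in blocks[[b]]) {
      raw <- lines[ln]
      parts <- strsplit(raw, ",")[[1]]
      if (length(parts) < 2L)
        stop(sprintf("line %d: expected 'name , genotypes'", ln))
      name <- trimws(parts[1])
      toks <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                       "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) != L)
        stop(sprintf("line %d: %d genotypes found but %d loci declared",
                     ln, length(toks), L))
      wl <- unique(nchar(toks))
      if (length(wl) != 1L || !(wl %in% c(4L, 6L)))
        stop(sprintf("line %d: malformed genotype width (expect 4 or 6 digits)",
                     ln))
      if (is.na(width)) width <- wl
      if (wl != width)
        stop(sprintf("line %d: genotype width %d differs from earlier lines (%d)",
                     ln, wl, width))
      if (any(grepl("[^0-9]", toks)))
        stop(sprintf("line %d: non-numeric genotype codes", ln))
      half <- width %/% 2L
      a1 <- as.integer(substr(toks, 1L, half))
      a2 <- as.integer(substr(toks, half + 1L, width))
      nm <- c(nm, name)
      gts[[length(gts) + 1L]] <- cbind(a1, a2)
      popidx <- c(popidx, b)
    }
    lastnames[b] <- trimws(strsplit(lines[blocks[[b]][length(blocks[[b]])]],
                                    ",")[[1]][1])
  }

  labels <- pop_names %||% lastnames
  if (length(labels) != length(blocks))
    stop("pop_names must have one label per population block")
  if (anyDuplicated(labels) || any(!nzchar(labels)))
    labels <- paste0("Pop", seq_along(blocks))

  n <- length(nm)
  al <- array(0L, dim = c(n, L, 2L))
  for (i in seq_len(n)) al[i, , ] <- gts[[i]]
  genotype_table(nm, factor(labels[popidx], levels = labels), al, loci)
}

#' Write a genotype table as a GENEPOP file
#'
#' @param gt a [genotype_table].
#' @param path output path.
#' @param title title line (first line of the file).
#' @param digits allele-code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "qstfst genotypes", digits = 3L) {
  stopifnot(digits %in% c(2L, 3L))
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gt$loci, con)
  for (p in levels(gt$pop)) {
    writeLines("Pop", con)
    sel <- which(gt$pop == p)
    for (i in sel) {
      g <- paste0(sprintf(fmt, gt$alleles[i, , 1]),
                  sprintf(fmt, gt$alleles[i, , 2]))
      # last individual of the block carries the population label so the
      # reader recovers it
      nm <- if (i == sel[length(sel)]) p else gt$ids[i]
      writeLines(paste0(nm, " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
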