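# Readers/writers for the two plain-text genotype formats used in SSR work
# (GenePop and the STRUCTURE two-rows-per-individual table) plus the
# population metadata CSV. No binning or recoding happens here.

#' Read a GenePop file
#'
#' Parses the classic GenePop dialect: a title line, one locus name per line
#' (or a single comma-separated line), population blocks introduced by a line
#' reading `POP` (case-insensitive), and per-individual lines
#' `id , g1 g2 ...` where each genotype is a concatenation of two 2- or
#' 3-digit allele codes and `00`/`000` codes a missing allele.
#'
#' Population labels are taken from the id of the first individual of each
#' block (the usual GenePop convention), or `pop_1`, `pop_2`, ... when ids
#' are uninformative.
#'
#' @param path file path.
#' @return a [genotype_dataset()] with populations in file order.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("GenePop parse error: file too short")
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (length(pop_idx) == 0)
    stop("GenePop parse error: no POP separator found")
  # locus names: lines 2 .. first POP - 1, possibly comma-separated on one line
  locus_lines <- lines[2:(pop_idx[1] - 1)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)
  if (L == 0) stop("GenePop parse error: no locus names before first POP")

  blocks <- Map(function(s, e) if (s > e) integer(0) else s:e,
                pop_idx + 1L,
                c(pop_idx[-1] - 1L, length(lines)))
  ids <- character(0); pops <- character(0)
  rows <- list()
  for (b in seq_along(blocks)) {
    ln <- blocks[[b]]
    ln <- ln[nzchar(trimws(lines[ln]))]
    if (length(ln) == 0)
      stop("GenePop parse error: empty population block ", b,
           " at line ", pop_idx[b])
    pop_label <- NULL
    for (i in ln) {
      parts <- strsplit(lines[i], ",")[[1]]
      if (length(parts) < 2)
        stop("GenePop parse error: missing ',' at line ", i)
      id <- trimws(parts[1])
      geno <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
      if (length(geno) != L)
        stop("GenePop parse error: expected ", L, " genotypes but found ",
             length(geno), " at line ", i)
      w <- unique(nchar(geno))
      if (length(w) != 1 || !(w %in% c(4L, 6L)))
        stop("GenePop parse error: odd allele-code length at line ", i)
      half <- w / 2L
      a1 <- as.integer(substr(geno, 1L, half))
      a2 <- as.integer(substr(geno, half + 1L, w))
      a1[a1 == 0L] <- NA_integer_
      a2[a2 == 0L] <- NA_integer_
      # treat half-calls as fully missing (no half-calls in the data model)
      drop <- is.na(a1) | is.na(a2)
      a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
      if (is.null(pop_label)) pop_label <- if (nzchar(id)) id else paste0("pop_", b)
      ids <- c(ids, id)
      pops <- c(pops, pop_label)
      rows[[length(rows) + 1L]] <- c(a1, a2)
    }
  }
  n <- length(rows)
  arr <- array(NA_integer_, dim = c(n, L, 2L))
  for (i in seq_len(n)) {
    arr[i, , 1L] <- rows[[i]][seq_len(L)]
    arr[i, , 2L] <- rows[[i]][L + seq_len(L)]
  }
  ids <- make.unique(ids)
  genotype_dataset(arr, individual_ids = ids, locus_names = locus_names,
                   pop = pops)
}

#' Write a GenePop file
#'
#' @param x a [genotype_dataset()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @param digits allele-code width, 2 or 3 (alleles must fit).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "ssrdemog export", digits = 3L) {
  stopifnot(digits %in% c(2L, 3L))
  mx <- suppressWarnings(max(x$alleles, na.rm = TRUE))
  if (is.finite(mx) && mx > 10^digits - 1)
    stop("allele size ", mx, " does not fit in ", digits, "-digit GenePop coding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(x$locus_names, con)
  fmt <- paste0("%0", digits, "d")
  code <- function(a) ifelse(is.na(a), paste0(sprintf(fmt, 0)), sprintf(fmt, a))
  for (p in unique(x$pop)) {
    writeLines("POP", con)
    for (i in which(x$pop == p)) {
      g <- paste0(code(x$alleles[i, , 1]), code(x$alleles[i, , 2]))
      writeLines(paste0(x$individual_ids[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a STRUCTURE two-rows-per-individual table
#'
#' Expects whitespace-separated rows `id pop a_1 ... a_L`, two consecutive
#' rows per individual (one per allele copy); `-9` codes a missing allele.
#'
#' @param path file path.
#' @param locus_names optional locus labels (defaults to `locus_1`, ...).
#' @return a [genotype_dataset()].
#' @export
read_structure_table <- function(path, locus_names = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) %% 2 != 0)
    stop("STRUCTURE parse error: odd number of rows (need 2 per individual)")
  if (ncol(tab) < 3)
    stop("STRUCTURE parse error: need id, pop and at least one locus column")
  L <- ncol(tab) - 2L
  n <- nrow(tab) / 2L
  r1 <- tab[2L * seq_len(n) - 1L, , drop = FALSE]
  r2 <- tab[2L * seq_len(n), , drop = FALSE]
  if (!all(r1[[1]] == r2[[1]]))
    stop("STRUCTURE parse error: consecutive row pairs have mismatching ids")
  arr <- array(NA_integer_, dim = c(n, L, 2L))
  arr[, , 1L] <- as.matrix(r1[, -(1:2), drop = FALSE])
  arr[, , 2L] <- as.matrix(r2[, -(1:2), drop = FALSE])
  arr[arr == -9L] <- NA_integer_
  half <- is.na(arr[, , 1L]) | is.na(arr[, , 2L])
  arr[, , 1L][half] <- NA_integer_
  arr[, , 2L][half] <- NA_integer_
  genotype_dataset(arr, individual_ids = as.character(r1[[1]]),
                   locus_names = locus_names,
                   pop = as.character(r1[[2]]))
}

#' Write a STRUCTURE two-rows-per-individual table
#'
#' @param x a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_table <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n_individuals(x))) {
    for (s in 1:2) {
      a <- x$alleles[i, , s]
      a[is.na(a)] <- -9L
      writeLines(paste(c(x$individual_ids[i], x$pop[i], a), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read the population metadata CSV
#'
#' Requires columns `population`, `species`, `latitude`, `longitude`,
#' `altitude` (degrees north, degrees east, metres above sea level).
#'
#' @param path file path.
#' @return a data frame, one row per population.
#' @export
read_metadata_csv <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "species", "latitude", "longitude", "altitude")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("metadata CSV missing columns: ", paste(miss, collapse = ", "))
  meta$latitude <- as.numeric(meta$latitude)
  meta$longitude <- as.numeric(meta$longitude)
  meta$altitude <- as.numeric(meta$altitude)
  meta
}
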