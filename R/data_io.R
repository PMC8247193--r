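#' Read and topologically sort a pedigree
#'
#' Reads a delimited text file with three id columns (animal, sire, dam) and
#' returns a pedigree sorted so that every parent precedes its offspring.
#' Parents that never occur in the animal column are appended as founders
#' with both parents unknown.
#'
#' @param path path to a delimited text file.
#' @param unknown_code token marking an unknown parent (default `"0"`).
#' @param header logical; does the file carry a header line?
#' @param sep field separator passed to [utils::read.table()] (default: any
#'   whitespace).
#' @return a `data.frame` with character columns `animal`, `sire`, `dam`
#'   (unknown parents are `NA`), in topological order.
#' @export
read_pedigree <- function(path, unknown_code = "0", header = TRUE, sep = "") {
  raw <- utils::read.table(path, header = header, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    return(data.frame(animal = character(), sire = character(),
                      dam = character(), stringsAsFactors = FALSE))
  }
  if (ncol(raw) < 3L) {
    stop_sswool("pedigree file needs >= 3 columns, found %d", ncol(raw),
                class = "sswool_format_error")
  }
  ped <- data.frame(animal = raw[[1L]], sire = raw[[2L]], dam = raw[[3L]],
                    stringsAsFactors = FALSE)
  ped$sire[ped$sire == unknown_code] <- NA_character_
  ped$dam[ped$dam == unknown_code] <- NA_character_
  sort_pedigree(ped)
}

#' Topologically sort a pedigree data frame
#'
#' @param ped data.frame with character columns `animal`, `sire`, `dam`
#'   (`NA` = unknown parent).
#' @return the pedigree reordered so parents precede offspring; unlisted
#'   parents are appended as founder records.
#' @export
sort_pedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$animal)) {
    stop_sswool("duplicate animal id(s): %s",
                paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "),
                class = "sswool_validation_error")
  }
  parents <- unique(c(ped$sire, ped$dam))
  parents <- parents[!is.na(parents) & !(parents %in% ped$animal)]
  if (length(parents)) {
    ped <- rbind(
      data.frame(animal = parents, sire = NA_character_, dam = NA_character_,
                 stringsAsFactors = FALSE),
      ped
    )
  }
  n <- nrow(ped)
  if (n == 0L) return(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  placed <- logical(n)
  order_out <- integer(n)
  filled <- 0L
  repeat {
    # a record is ready when each known parent is already placed
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) break
    order_out[filled + seq_along(ready)] <- ready
    filled <- filled + length(ready)
    placed[ready] <- TRUE
  }
  if (filled < n) {
    # walk parent pointers from an unplaced node to exhibit a cycle
    start <- which(!placed)[1L]
    path <- integer(0); cur <- start
    while (!(cur %in% path)) {
      path <- c(path, cur)
      nxt <- c(si[cur], di[cur])
      nxt <- nxt[!is.na(nxt) & !placed[nxt]]
      cur <- nxt[1L]
    }
    cyc <- ped$animal[path[which(path == cur)[1L]:length(path)]]
    stop_sswool("pedigree cycle detected: %s", paste(cyc, collapse = " -> "),
                class = "sswool_structural_error")
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pedigree as tab-separated text
#'
#' @param ped pedigree data.frame (see [read_pedigree()]).
#' @param path output path.
#' @param unknown_code token written for unknown parents.
#' @export
write_pedigree <- function(ped, path, unknown_code = "0") {
  out <- ped
  out$sire[is.na(out$sire)] <- unknown_code
  out$dam[is.na(out$dam)] <- unknown_code
  write_table(out, path)
}

# ---- PLINK genotype formats -------------------------------------------------

#' Read genotypes in PLINK text or binary layout
#'
#' Supports the classic `.ped`/`.map` text pair and the SNP-major binary
#' `.bed`/`.bim`/`.fam` triplet (magic bytes `0x6c 0x1b 0x01`). Dosage counts
#' the A1 allele: for binary input A1 is column 5 of the `.bim`; for text
#' input, where the `.map` carries no alleles, A1 is the lexicographically
#' smallest allele observed at the marker (a deterministic convention,
#' recorded in the returned map).
#'
#' @param path_prefix path without extension.
#' @param dialect `"plink_text"` or `"plink_bed"`.
#' @return a list with `genotypes` (integer matrix, individuals x markers,
#'   entries 0/1/2 or `NA`, dimnames = ids) and `map` (data.frame `snp`,
#'   `chrom`, `pos`, `a1`, `a2`).
#' @export
read_genotypes <- function(path_prefix, dialect = c("plink_text", "plink_bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "plink_text") read_plink_text(path_prefix) else read_plink_bed(path_prefix)
}

read_plink_text <- function(prefix) {
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  map_raw <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  m <- nrow(map_raw)
  ped_raw <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped_raw) != 6L + 2L * m) {
    stop_sswool(".ped has %d genotype columns but .map declares %d markers",
                ncol(ped_raw) - 6L, m, class = "sswool_format_error")
  }
  n <- nrow(ped_raw)
  ids <- ped_raw[[2L]]
  al1 <- as.matrix(ped_raw[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  al2 <- as.matrix(ped_raw[, 6L + 2L * seq_len(m), drop = FALSE])
  al1[al1 == "0"] <- NA; al2[al2 == "0"] <- NA
  geno <- matrix(NA_integer_, n, m, dimnames = list(ids, map_raw[[2L]]))
  a1 <- a2 <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- sort(unique(stats::na.omit(c(al1[, j], al2[, j]))))
    if (length(obs) > 2L) {
      stop_sswool("marker %s has >2 alleles: %s", map_raw[j, 2L],
                  paste(obs, collapse = ","), class = "sswool_format_error")
    }
    a1[j] <- if (length(obs) >= 1L) obs[1L] else NA_character_
    a2[j] <- if (length(obs) == 2L) obs[2L] else NA_character_
    dose <- (al1[, j] == a1[j]) + (al2[, j] == a1[j])
    dose[is.na(al1[, j]) | is.na(al2[, j])] <- NA
    geno[, j] <- as.integer(dose)
  }
  map <- data.frame(snp = map_raw[[2L]], chrom = map_raw[[1L]],
                    pos = as.integer(map_raw[[4L]]),
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  list(genotypes = geno, map = map)
}

read_plink_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = "character")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  m <- nrow(bim); n <- nrow(fam)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop_sswool(".bed magic bytes wrong (not SNP-major v1.0)",
                class = "sswool_format_error")
  }
  bpm <- ceiling(n / 4)
  raw <- readBin(con, "raw", bpm * m)
  if (length(raw) != bpm * m) {
    stop_sswool(".bed truncated: expected %d data bytes, got %d",
                bpm * m, length(raw), class = "sswool_format_error")
  }
  # unpack 2-bit codes, LSB first: 00=hom A1, 01=missing, 10=het, 11=hom A2
  bits <- matrix(as.integer(rawToBits(raw)), nrow = 2L)
  codes <- bits[1L, ] + 2L * bits[2L, ]             # per 2-bit slot
  codes <- matrix(codes, nrow = 4L * bpm)[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  geno <- matrix(lut[codes + 1L], n, m,
                 dimnames = list(fam[[2L]], bim[[2L]]))
  map <- data.frame(snp = bim[[2L]], chrom = bim[[1L]],
                    pos = as.integer(bim[[4L]]),
                    a1 = bim[[5L]], a2 = bim[[6L]], stringsAsFactors = FALSE)
  list(genotypes = geno, map = map)
}

#' Write genotypes in PLINK text or binary layout
#'
#' @param genotypes integer matrix individuals x markers (0/1/2/NA), with
#'   dimnames.
#' @param map marker map data.frame (`snp`, `chrom`, `pos`; optional `a1`,
#'   `a2`, defaulting to `"A"`/`"C"`).
#' @param path_prefix output path without extension.
#' @param dialect `"plink_text"` or `"plink_bed"`.
#' @return `path_prefix`, invisibly.
#' @export
write_genotypes <- function(genotypes, map,
                            path_prefix, dialect = c("plink_text", "plink_bed")) {
  dialect <- match.arg(dialect)
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(nrow(map) == m)
  a1 <- map$a1 %||% rep("A", m); a2 <- map$a2 %||% rep("C", m)
  a1[is.na(a1)] <- "A"; a2[is.na(a2)] <- "C"
  ids <- rownames(genotypes) %||% as.character(seq_len(n))
  if (dialect == "plink_text") {
    map_df <- data.frame(map$chrom, map$snp, 0L, map$pos)
    utils::write.table(map_df, paste0(path_prefix, ".map"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    allele_cols <- matrix("0", n, 2L * m)
    for (j in seq_len(m)) {
      g <- genotypes[, j]
      c1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a1[j], a2[j]))
      c2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a1[j], a2[j]))
      allele_cols[, 2L * j - 1L] <- c1
      allele_cols[, 2L * j] <- c2
    }
    ped_df <- cbind(data.frame(fid = ids, iid = ids, pat = 0L, mat = 0L,
                               sex = 0L, pheno = -9L),
                    as.data.frame(allele_cols))
    utils::write.table(ped_df, paste0(path_prefix, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(
      data.frame(map$chrom, map$snp, 0L, map$pos, a1, a2),
      paste0(path_prefix, ".bim"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(ids, ids, 0L, 0L, 0L, -9L),
      paste0(path_prefix, ".fam"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    con <- file(paste0(path_prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    bpm <- ceiling(n / 4)
    code_of <- function(g) ifelse(is.na(g), 1L, c(3L, 2L, 0L)[g + 1L])
    for (j in seq_len(m)) {
      codes <- c(code_of(genotypes[, j]), rep(0L, 4L * bpm - n))
      b <- codes[seq(1L, length(codes), 4L)] +
        4L * codes[seq(2L, length(codes), 4L)] +
        16L * codes[seq(3L, length(codes), 4L)] +
        64L * codes[seq(4L, length(codes), 4L)]
      writeBin(as.raw(b), con)
    }
  }
  invisible(path_prefix)
}

# ---- Gene annotation --------------------------------------------------------

#' Read a gene annotation from BED or GFF3
#'
#' Coordinates are normalised to the package-wide 1-based inclusive
#' convention: BED starts (0-based half-open) are incremented by one on
#' import; GFF3 coordinates pass through unchanged. Strand is stored but
#' ignored by marker-to-gene mapping.
#'
#' @param path input file.
#' @param dialect `"bed"` or `"gff3"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    raw <- utils::read.table(path, header = FALSE, sep = "",
                             colClasses = "character", comment.char = "#")
    if (ncol(raw) < 4L) {
      stop_sswool("BED needs >= 4 columns (BED4+)", class = "sswool_format_error")
    }
    ann <- data.frame(
      gene_id = raw[[4L]], chrom = raw[[1L]],
      start = as.integer(raw[[2L]]) + 1L, end = as.integer(raw[[3L]]),
      strand = if (ncol(raw) >= 6L) raw[[6L]] else "*",
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                             colClasses = "character", comment.char = "#")
    if (ncol(raw) < 9L) {
      stop_sswool("GFF3 needs 9 tab-separated columns", class = "sswool_format_error")
    }
    keep <- raw[[3L]] == "gene"
    if (!any(keep)) keep <- rep(TRUE, nrow(raw))
    raw <- raw[keep, , drop = FALSE]
    ids <- vapply(raw[[9L]], function(attr) {
      for (key in c("ID=", "gene_id=", "Name=")) {
        hit <- regmatches(attr, regexec(paste0(key, "([^;]+)"), attr))[[1L]]
        if (length(hit) == 2L) return(sub("^gene:", "", hit[2L]))
      }
      attr
    }, character(1), USE.NAMES = FALSE)
    ann <- data.frame(gene_id = ids, chrom = raw[[1L]],
                      start = as.integer(raw[[4L]]), end = as.integer(raw[[5L]]),
                      strand = raw[[7L]], stringsAsFactors = FALSE)
  }
  bad <- ann$end < ann$start
  if (any(bad)) {
    stop_sswool("gene(s) with end < start after normalisation: %s",
                paste(ann$gene_id[bad], collapse = ", "),
                class = "sswool_format_error")
  }
  rownames(ann) <- NULL
  ann
}

#' Write a result table as deterministic tab-separated text
#'
#' Byte-for-byte reproducible given the same input: fixed column order (as
#' passed), no quoting, no row names, `NA` written as empty string.
#'
#' @param records a data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  stopifnot(!is.null(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
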