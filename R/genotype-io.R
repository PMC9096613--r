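# Reading, writing, validating, filtering and subsampling genotype matrices,
# field maps and family tables.
#
# The genotype container is a plain integer matrix: rows = individuals,
# columns = loci (locus ids carry a chromosome prefix, e.g. "C03_0012000"),
# entries = dosage of the counted allele (0/1/2) or NA.

.validate_gm <- function(gm) {
  if (!is.matrix(gm) || is.null(rownames(gm)) || is.null(colnames(gm))) {
    stop("genotype matrix must have individual rownames and locus colnames")
  }
  if (anyDuplicated(rownames(gm))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(gm))) stop("duplicate locus ids")
  .check_dosage(gm, "genotype call")
  invisible(gm)
}

#' Read a genotype matrix from VCF or a TSV dosage table
#'
#' The VCF dialect uses the GT field only; `0/0`, `0/1`, `1/1` (or phased
#' variants) map to dosages 0, 1, 2 of the ALT allele and `./.` to missing.
#' Multi-allelic records are rejected. The TSV dialect is individuals x loci
#' with an `id` first column and cells 0/1/2/NA.
#'
#' @param path file path.
#' @param dialect "auto" (by extension), "vcf" or "tsv".
#' @return integer dosage matrix (individuals x loci).
#' @export
read_genotypes <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- v@fix[, "ALT"]
    if (any(grepl(",", alt, fixed = TRUE))) {
      stop("multi-allelic VCF records are not supported; split or drop them first")
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos[gt %in% c("0/0")] <- 0L
    dos[gt %in% c("0/1", "1/0")] <- 1L
    dos[gt %in% c("1/1")] <- 2L
    unknown <- !is.na(gt) & is.na(dos) & gt != "./." & gt != "."
    if (any(unknown)) {
      stop("unparseable GT value(s), e.g. ", gt[which(unknown)[1]])
    }
    gm <- t(dos)
    rownames(gm) <- colnames(gt)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "id") stop("TSV dosage table must start with an 'id' column")
    gm <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(gm) <- "integer"
    rownames(gm) <- tab$id
  }
  .validate_gm(gm)
  message(sprintf("read %d individuals x %d loci from %s",
                  nrow(gm), ncol(gm), basename(path)))
  gm
}

#' Write a genotype matrix as VCF (GT-only) or TSV dosage table
#'
#' @param gm dosage matrix (individuals x loci).
#' @param path output path.
#' @param dialect "vcf" or "tsv".
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  .validate_gm(gm)
  if (dialect == "tsv") {
    tab <- data.frame(id = rownames(gm), gm, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  loci <- colnames(gm)
  chrom <- sub("_.*$", "", loci)
  pos <- suppressWarnings(as.integer(sub("^.*_", "", loci)))
  if (anyNA(pos)) pos <- seq_along(loci)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", ncol(gm), nrow(gm))
  typed <- !is.na(t(gm))
  gt[typed] <- code[as.character(t(gm)[typed])]
  body <- paste(chrom, pos, loci, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pollenkin",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Per-locus frequency of the counted allele
#'
#' @param gm dosage matrix.
#' @param individuals optional subset of individual ids or indices.
#' @return numeric vector of frequencies among non-missing calls; NA at loci
#'   with no data.
#' @export
allele_frequencies <- function(gm, individuals = NULL) {
  if (!is.null(individuals)) gm <- gm[individuals, , drop = FALSE]
  if (nrow(gm) == 0) stop("empty individual subset")
  colMeans(gm, na.rm = TRUE) / 2
}

#' Filter loci on minor-allele frequency and missingness
#'
#' Retains loci with minor-allele frequency at least `maf_min` (computed on
#' non-missing calls over all individuals supplied) and a missing-call
#' fraction of at most `max_missing` (the boundary is kept: the discard rule
#' is strictly greater than).
#'
#' @param gm dosage matrix.
#' @param maf_min minimum minor-allele frequency.
#' @param max_missing maximum tolerated missing fraction per locus.
#' @return filtered matrix, with a `filter_report` attribute giving dropped
#'   counts per rule.
#' @export
filter_loci <- function(gm, maf_min = 0.03, max_missing = 0.10) {
  if (ncol(gm) == 0) stop("empty genotype matrix")
  p <- allele_frequencies(gm)
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(gm))
  keep_maf <- !is.na(maf) & maf >= maf_min
  keep_miss <- miss <= max_missing
  keep <- keep_maf & keep_miss
  if (!any(keep)) warning("all loci removed by filtering")
  out <- gm[, keep, drop = FALSE]
  attr(out, "filter_report") <- c(
    n_input = ncol(gm),
    dropped_maf = sum(!keep_maf),
    dropped_missing = sum(!keep_miss),
    n_kept = sum(keep)
  )
  out
}

#' Randomly subsample loci without replacement
#'
#' @param gm dosage matrix.
#' @param n loci to retain.
#' @param seed integer seed (deterministic subset).
#' @return matrix with `n` loci in their original order.
#' @export
subsample_loci <- function(gm, n = 2500, seed = 1) {
  if (n > ncol(gm)) stop("n exceeds the available locus count")
  set.seed(as.integer(seed))
  keep <- sort(sample.int(ncol(gm), n))
  gm[, keep, drop = FALSE]
}

#' Read / write a field map (genet coordinates) as CSV
#'
#' Columns: genet_id, family_id, role (candidate/mother/border), grid_row,
#' grid_col, x_m, y_m.
#' @param path CSV path.
#' @return data frame.
#' @export
read_field_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genet_id", "family_id", "role", "x_m", "y_m")
  if (!all(need %in% names(map))) {
    stop("field map must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$genet_id)) stop("duplicate genet_id in field map")
  if (any(!is.finite(map$x_m)) || any(!is.finite(map$y_m))) {
    stop("field map coordinates must be finite")
  }
  message(sprintf("read %d genets from %s", nrow(map), basename(path)))
  map
}

#' @rdname read_field_map
#' @param map field map data frame.
#' @export
write_field_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a progeny-to-mother family table as CSV
#'
#' Columns: progeny_id, mother_id.
#' @param path CSV path.
#' @param map optional field map; when given, mothers are checked against it.
#' @return data frame.
#' @export
read_family_table <- function(path, map = NULL) {
  fam <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("progeny_id", "mother_id") %in% names(fam))) {
    stop("family table must contain progeny_id and mother_id")
  }
  if (anyDuplicated(fam$progeny_id)) stop("duplicate progeny_id in family table")
  if (!is.null(map) && !all(fam$mother_id %in% map$genet_id)) {
    stop("family table references mothers absent from the field map")
  }
  message(sprintf("read %d progeny from %s", nrow(fam), basename(path)))
  fam
}

#' @rdname read_family_table
#' @param fam family table data frame.
#' @export
write_family_table <- function(fam, path) {
  utils::write.csv(fam, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
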