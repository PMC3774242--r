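#' Write and read the RIL cross files
#'
#' Genotype CSV in the classic cross layout with three header rows — marker
#' name, chromosome, cM position — then one row per line with genotypes
#' coded `A` / `B` / `NA`. Phenotypes go in a plain CSV keyed by line id.
#' All files are comma-separated UTF-8 with '.' decimal and 'NA' missing.
#'
#' @param panel a `ril_panel`.
#' @param geno_file,pheno_file output paths.
#' @return invisibly, the file paths.
#' @export
write_cross <- function(panel, geno_file, pheno_file) {
  map <- panel$map
  geno <- panel$geno[, map$marker, drop = FALSE]
  codes <- matrix(c("B", "A")[geno + 1L], nrow(geno))
  codes[is.na(geno)] <- "NA"
  lines_out <- c(
    paste(c("id", map$marker), collapse = ","),
    paste(c("", map$chrom), collapse = ","),
    paste(c("", format(map$pos, trim = TRUE, digits = 12)), collapse = ","),
    vapply(seq_len(nrow(geno)),
           function(i) paste(c(rownames(geno)[i], codes[i, ]),
                             collapse = ","),
           character(1))
  )
  writeLines(lines_out, geno_file)
  utils::write.csv(panel$pheno, pheno_file, row.names = FALSE, na = "NA")
  invisible(c(geno_file, pheno_file))
}

#' @rdname write_cross
#' @param map_scale scale of the map distances in the file (`"ril"` for
#'   maps estimated from RIL data, `"meiotic"` for simulator output).
#' @return `read_cross`: list(map, panel) with phenotypes joined by id.
#' @export
read_cross <- function(geno_file, pheno_file,
                       map_scale = c("ril", "meiotic")) {
  map_scale <- match.arg(map_scale)
  raw <- utils::read.csv(geno_file, header = FALSE,
                         colClasses = "character", na.strings = NULL)
  if (nrow(raw) < 4) stop("genotype file lacks the three header rows")
  markers <- as.character(raw[1, -1])
  chrom <- as.character(raw[2, -1])
  pos <- suppressWarnings(as.numeric(raw[3, -1]))
  if (anyNA(pos)) stop("non-numeric cM positions in header row 3")
  map <- genetic_map(markers, chrom, pos, map_scale = map_scale)
  body <- raw[-(1:3), , drop = FALSE]
  ids <- body[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated line ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  codes <- as.matrix(body[, -1, drop = FALSE])
  bad <- setdiff(unique(as.vector(codes)), c("A", "B", "NA", ""))
  if (length(bad)) stop("unknown genotype codes: ",
                        paste(bad, collapse = ", "))
  geno <- matrix(NA_integer_, nrow(codes), ncol(codes),
                 dimnames = list(ids, markers))
  geno[codes == "A"] <- 1L
  geno[codes == "B"] <- 0L
  geno <- geno[, map$marker, drop = FALSE]
  pheno <- utils::read.csv(pheno_file, stringsAsFactors = FALSE)
  if (anyDuplicated(pheno$id)) stop("duplicated phenotype line ids")
  pheno <- pheno[match(ids, pheno$id), , drop = FALSE]
  rownames(pheno) <- NULL
  panel <- structure(list(geno = geno, pheno = pheno, map = map),
                     class = "ril_panel")
  list(map = map, panel = panel)
}

#' Write an SNP panel as a minimal VCF
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, FORMAT and one GT
#' column per accession, with haploid-coded homozygote calls (`0`, `1`,
#' `.` for missing).
#'
#' @param panel an [snp_panel()].
#' @param file output path (`.vcf`).
#' @return invisibly, the file path.
#' @export
write_snp_vcf <- function(panel, file) {
  gt <- matrix(".", nrow(panel$geno), ncol(panel$geno))
  gt[!is.na(panel$geno)] <- as.character(panel$geno[!is.na(panel$geno)])
  header <- c("##fileformat=VCFv4.2",
              "##source=pleioscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(panel$geno)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(panel$snps)), function(j) {
    paste(c(panel$snps$chrom[j], panel$snps$pos[j], panel$snps$id[j],
            "A", "T", ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Write an SNP panel as a delimited 0/1 matrix
#'
#' Same three-header-row layout as the cross genotype file (SNP id,
#' chromosome, bp position), one row per accession, entries 0/1/NA.
#'
#' @param panel an [snp_panel()].
#' @param file output path (`.csv`).
#' @return invisibly, the file path.
#' @export
write_snp_matrix <- function(panel, file) {
  vals <- matrix(as.character(panel$geno), nrow(panel$geno))
  vals[is.na(panel$geno)] <- "NA"
  lines_out <- c(
    paste(c("id", panel$snps$id), collapse = ","),
    paste(c("", panel$snps$chrom), collapse = ","),
    paste(c("", panel$snps$pos), collapse = ","),
    vapply(seq_len(nrow(panel$geno)),
           function(i) paste(c(rownames(panel$geno)[i], vals[i, ]),
                             collapse = ","), character(1))
  )
  writeLines(lines_out, file)
  invisible(file)
}

#' Write/read the accession metadata table
#'
#' @param panel an [snp_panel()].
#' @param file CSV path (columns id, class, cluster, lat, lon).
#' @export
write_accessions <- function(panel, file) {
  utils::write.csv(panel$accessions, file, row.names = FALSE, na = "NA")
  invisible(file)
}

#' Read an SNP panel from VCF or delimited matrix
#'
#' VCF: biallelic records only (multi-allelic records are skipped and
#' counted); GT is parsed haploid or diploid-homozygous; heterozygous calls
#' are set missing with a warning (the accessions are inbred). Delimited:
#' the three-header-row matrix written by [write_snp_matrix()].
#'
#' @param file `.vcf` or matrix `.csv` path (format inferred from the
#'   extension unless given).
#' @param accessions optional metadata: a data frame or CSV path with
#'   columns id, class, and optionally cluster, lat, lon.
#' @param format `"auto"`, `"vcf"` or `"matrix"`.
#' @param focal optional list(chrom, bp).
#' @return an [snp_panel()].
#' @export
read_snp_panel <- function(file, accessions = NULL,
                           format = c("auto", "vcf", "matrix"),
                           focal = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", file)) "vcf" else "matrix"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi)) {
      message(sum(multi), " multi-allelic record(s) skipped")
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    parse_one <- function(s) {
      if (is.na(s) || s == "." || s == "./." || s == ".|.") return(NA_integer_)
      al <- strsplit(s, "[/|]")[[1]]
      al <- al[al != "."]
      if (!length(al)) return(NA_integer_)
      u <- unique(al)
      if (length(u) > 1) return(-1L)  # heterozygous sentinel
      as.integer(u)
    }
    G <- vapply(seq_len(ncol(gt)),
                function(j) vapply(gt[, j], parse_one, integer(1),
                                   USE.NAMES = FALSE),
                integer(nrow(gt)))
    if (is.null(dim(G))) G <- matrix(G, nrow = nrow(gt))
    n_het <- sum(G == -1L, na.rm = TRUE)
    if (n_het > 0) {
      warning(n_het, " heterozygous call(s) set to missing (inbred panel)")
      G[G == -1L] <- NA_integer_
    }
    geno <- t(G)
    rownames(geno) <- colnames(gt)
    snps <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       stringsAsFactors = FALSE)
    colnames(geno) <- snps$id
  } else {
    raw <- utils::read.csv(file, header = FALSE, colClasses = "character",
                           na.strings = NULL)
    if (nrow(raw) < 4) stop("matrix file lacks the three header rows")
    snps <- data.frame(id = as.character(raw[1, -1]),
                       chrom = as.character(raw[2, -1]),
                       pos = as.integer(raw[3, -1]),
                       stringsAsFactors = FALSE)
    body <- raw[-(1:3), , drop = FALSE]
    vals <- as.matrix(body[, -1, drop = FALSE])
    bad <- setdiff(unique(as.vector(vals)), c("0", "1", "NA", ""))
    if (length(bad)) stop("unknown genotype values: ",
                          paste(bad, collapse = ", "))
    geno <- matrix(NA_integer_, nrow(vals), ncol(vals))
    geno[vals == "0"] <- 0L
    geno[vals == "1"] <- 1L
    rownames(geno) <- body[[1]]
    colnames(geno) <- snps$id
  }
  ord <- order(match(snps$chrom, unique(snps$chrom)), snps$pos)
  geno <- geno[, ord, drop = FALSE]
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  if (is.character(accessions)) {
    accessions <- utils::read.csv(accessions, stringsAsFactors = FALSE)
  }
  if (is.null(accessions)) {
    accessions <- data.frame(id = rownames(geno), class = NA_character_,
                             stringsAsFactors = FALSE)
  } else {
    accessions <- accessions[match(rownames(geno), accessions$id), ,
                             drop = FALSE]
    rownames(accessions) <- NULL
  }
  snp_panel(geno, snps, accessions, focal = focal)
}

#' Serialize and restore a ground-truth record
#'
#' @param truth a truth list from the simulators.
#' @param file JSON path.
#' @export
write_truth <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
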