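#' Write phased genotypes to a VCF file
#'
#' Minimal VCF 4.2 with phased GT fields; the first allele of each
#' genotype is the paternal one (package convention). Placeholder REF/ALT
#' bases are written since the simulator tracks abstract 0/1 alleles.
#'
#' @param geno [PhasedGenotypes-class].
#' @param path output file.
#' @export
writePhasedVcf <- function(geno, path) {
  map <- snpMap(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=boaGBLUP",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", animalIds(geno)),
                     collapse = "\t")), con)
  gt <- matrix(paste0(t(geno@pat), "|", t(geno@mat)),
               nrow = nSnps(geno))
  body <- paste(map$chrom, map$pos, map$id, "A", "G", ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read phased genotypes from a VCF file
#'
#' Accepts biallelic SNPs with fully phased GT fields ("|" separator);
#' unphased records are an error naming the first offending record, and
#' multiallelic sites are skipped with a message. 1-based positions are
#' preserved.
#'
#' @param path VCF file (plain text or gzipped).
#' @return [PhasedGenotypes-class].
#' @export
readPhasedVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
    id <- fix[, "ID"]; alt <- fix[, "ALT"]
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    cols <- strsplit(lines[hdr], "\t")[[1]]
    rec <- strsplit(lines[(hdr + 1):length(lines)], "\t")
    tab <- do.call(rbind, rec)
    chrom <- tab[, 1]; pos <- as.integer(tab[, 2]); id <- tab[, 3]
    alt <- tab[, 5]
    gt <- tab[, -(1:9), drop = FALSE]
    colnames(gt) <- cols[-(1:9)]
    gt <- sub(":.*", "", gt)
  }
  multi <- grepl(",", alt)
  if (any(multi)) {
    message(sum(multi), " multiallelic site(s) skipped")
    chrom <- chrom[!multi]; pos <- pos[!multi]; id <- id[!multi]
    gt <- gt[!multi, , drop = FALSE]
  }
  bad <- grepl("/", gt, fixed = TRUE)
  dim(bad) <- dim(gt)
  unphased <- which(bad, arr.ind = TRUE)
  if (nrow(unphased)) {
    stop("unphased genotype at SNP ", id[unphased[1, 1]],
         ", sample ", colnames(gt)[unphased[1, 2]], call. = FALSE)
  }
  pat <- t(matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt)))
  mat <- t(matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt)))
  rownames(pat) <- rownames(mat) <- colnames(gt)
  phasedGenotypes(pat, mat, markerMap(chrom, pos, id))
}

#' Write / read breed-of-origin labels as TSV
#'
#' Long format: `animal`, `snp`, `gamete` (pat/mat), `origin`.
#' @param origins [OriginMatrix-class].
#' @param geno matching [PhasedGenotypes-class] (for SNP ids).
#' @param path file path.
#' @export
writeOriginTsv <- function(origins, geno, path) {
  lab <- originLabels(origins)
  ids <- animalIds(geno); snps <- snpMap(geno)$id
  df <- data.frame(
    animal = rep(rep(ids, each = length(snps)), 2),
    snp = rep(snps, 2 * length(ids)),
    gamete = rep(c("pat", "mat"), each = length(ids) * length(snps)),
    origin = c(t(lab$pat), t(lab$mat)))
  df$origin[is.na(df$origin)] <- "missing"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOriginTsv
#' @export
readOriginTsv <- function(path, geno) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  ids <- animalIds(geno); snps <- snpMap(geno)$id
  shape <- function(side) {
    sub <- df[df$gamete == side, ]
    m <- matrix(NA_character_, length(ids), length(snps),
                dimnames = list(ids, snps))
    m[cbind(match(sub$animal, ids), match(sub$snp, snps))] <- sub$origin
    m[m == "missing"] <- NA_character_
    m
  }
  originMatrix(shape("pat"), shape("mat"))
}

#' Write a pipeline report
#'
#' Serialises the report bundle as pretty JSON with stable key order and
#' 10 significant digits, plus TSV tables for block and SNP-effect
#' results. Re-serialisation of the same report is byte-identical.
#'
#' @param report list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  tables <- report$tables
  report$tables <- NULL
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null", null = "null")
  writeLines(json, paths[1])
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write pedigree, phenotype and marker-map tables
#'
#' Plain-text writers for the remaining study tables: pedigree CSV
#' (`id,sire,dam,group,litter`), phenotype CSV (all record columns), and
#' marker map TSV (`chrom`, `pos`, `id`, `is_focal`, `on_panel`).
#'
#' @param ped,records,map the respective tables.
#' @param path output file.
#' @export
writePedigreeCsv <- function(ped, path) {
  write.table(ped[, c("id", "sire", "dam", "group", "litter")], path,
              sep = ",", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writePedigreeCsv
#' @export
writePhenotypesCsv <- function(records, path) {
  write.table(records, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname writePedigreeCsv
#' @export
writeMarkerMapTsv <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
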