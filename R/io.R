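# Dataset I/O: VCF with per-sample dosages, trio-mapping TSV, phenotype TSV.
# Reading goes through vcfR; writing emits plain VCF v4.2 text (GT:DS).

#' Write a simulated cohort to disk
#'
#' Emits three files that round-trip losslessly through the package readers:
#' a VCF v4.2 with GT and DS (effect-allele dosage) per sample (mother,
#' father and child of each trio are separate sample columns), a
#' trio-mapping TSV (`family_id`, `individual_id`, `role`), and a phenotype
#' TSV. The cohort must have been simulated in genotype mode.
#'
#' @param cohort A `bw_trio_cohort` with genotypes.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"cohort"`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "bw_trio_cohort"))
  if (is.null(cohort$genotypes))
    stop("cohort has no genotypes; simulate with mode = \"genotype\"")
  if (nrow(cohort$phenotypes) == 0 || nrow(cohort$genotypes$mother) == 0)
    stop("empty cohort: nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             trios = file.path(dir, paste0(prefix, "_trios.tsv")),
             phenotypes = file.path(dir, paste0(prefix, "_phenotypes.tsv")))

  ids <- cohort$phenotypes$trio_id
  map <- tibble::tibble(
    family_id = rep(ids, each = 3),
    individual_id = paste(rep(ids, each = 3),
                          rep(c("mother", "father", "child"), length(ids)),
                          sep = "_"),
    role = rep(c("mother", "father", "child"), length(ids))
  )
  write_trio_vcf(cohort$genotypes, cohort$weights, map, paths[["vcf"]])
  utils::write.table(map, paths[["trios"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_phenotypes(cohort$phenotypes, paths[["phenotypes"]])
  invisible(paths)
}

# Plain-text VCF emitter; REF = other allele, ALT = effect (counted) allele.
write_trio_vcf <- function(genotypes, weights, map, path) {
  n_snps <- ncol(genotypes$mother)
  if (is.null(weights)) {
    weights <- tibble::tibble(snp_id = colnames(genotypes$mother),
                              chrom = "1", pos = seq_len(n_snps),
                              effect_allele = "A", other_allele = "G")
  }
  # samples in map order; dosage matrix variants x samples
  role_mat <- list(mother = genotypes$mother, father = genotypes$father,
                   child = genotypes$child)
  fam_idx <- match(map$family_id, unique(map$family_id))
  dos <- vapply(seq_len(nrow(map)), function(i)
    role_mat[[map$role[i]]][fam_idx[i], ], numeric(n_snps))
  gt <- matrix("./.", nrow = n_snps, ncol = nrow(map))
  hard <- dos == round(dos)
  gt[hard] <- c("0/0", "0/1", "1/1")[round(dos[hard]) + 1L]
  body <- matrix(paste0(gt, ":", format(dos, trim = TRUE, digits = 6)),
                 nrow = n_snps)
  fixed <- paste(weights$chrom, weights$pos, weights$snp_id,
                 weights$other_allele, weights$effect_allele,
                 ".", "PASS", ".", "GT:DS", sep = "\t")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=bwtrio",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", map$individual_id), collapse = "\t"),
    paste(fixed, apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read trio genotypes from a VCF and a trio-mapping TSV
#'
#' Extracts per-sample dosages (DS field; falls back to counting alternate
#' alleles in GT) and splits them into mother/father/child matrices using
#' the mapping file. Dosages count the VCF's ALT allele; use
#' [align_dosages()] to orient them to a weights table.
#'
#' @param vcf_path Path to a VCF (v4.x, plain or gzipped).
#' @param map_path Path to a TSV with columns `family_id`, `individual_id`,
#'   `role` (mother/father/child).
#' @return A `bw_trio_genotypes` list: `mother`, `father`, `child` dosage
#'   matrices (families x SNPs), `variants` tibble (`snp_id`, `chrom`,
#'   `pos`, `counted_allele` = ALT, `other_allele` = REF), `trio_ids`.
#' @export
read_trio_vcf <- function(vcf_path, map_path) {
  map <- utils::read.delim(map_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("family_id", "individual_id", "role")
  if (!all(need %in% names(map)))
    stop("trio map must have columns: ", paste(need, collapse = ", "))
  if (!all(map$role %in% c("mother", "father", "child")))
    stop("trio map roles must be mother/father/child")

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gtc <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      out <- rep(NA_real_, length(g))
      ok <- !is.na(g) & !grepl("\\.", g)
      out[ok] <- vapply(strsplit(g[ok], "[/|]"),
                        function(a) sum(a == "1"), numeric(1))
      out
    }
    ds <- apply(gtc, 2, count_alt)
    dim(ds) <- dim(gtc); dimnames(ds) <- dimnames(gtc)
  }
  variants <- tibble::tibble(
    snp_id = v@fix[, "ID"], chrom = v@fix[, "CHROM"],
    pos = as.integer(v@fix[, "POS"]),
    counted_allele = v@fix[, "ALT"], other_allele = v@fix[, "REF"]
  )
  absent <- setdiff(map$individual_id, colnames(ds))
  if (length(absent))
    stop("trio-map individual(s) absent from VCF: ",
         paste(utils::head(absent, 5), collapse = ", "))

  fams <- unique(map$family_id)
  pick <- function(role) {
    sub <- map[map$role == role, ]
    sub <- sub[match(fams, sub$family_id), ]
    m <- t(ds[, sub$individual_id, drop = FALSE])
    dimnames(m) <- list(fams, variants$snp_id)
    m
  }
  structure(list(mother = pick("mother"), father = pick("father"),
                 child = pick("child"), variants = variants,
                 trio_ids = fams),
            class = "bw_trio_genotypes")
}

#' Write / read the phenotype table
#'
#' The TSV stores offspring sex as `male`/`female`; the reader restores the
#' numeric `sex_male` indicator used in design matrices.
#'
#' @param phenotypes Phenotype tibble (as in `bw_trio_cohort$phenotypes`).
#' @param path TSV path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- as.data.frame(phenotypes)
  if ("sex_male" %in% names(out)) {
    out$sex <- ifelse(out$sex_male == 1, "male", "female")
    out$sex_male <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  if ("sex" %in% names(ph)) {
    bad <- !ph$sex %in% c("male", "female")
    if (any(bad)) stop("sex must be male/female; got: ",
                       paste(unique(ph$sex[bad]), collapse = ", "))
    ph$sex_male <- as.integer(ph$sex == "male")
    ph$sex <- NULL
  }
  ph
}
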