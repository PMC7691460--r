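# Readers and writers for the interchange formats (genotype TSV,
# PLINK-RAW, VCF with GT fields, pedigree/phenotype CSV, truth JSON) and
# the end-to-end pipeline driver.

#' Read a genotype matrix
#'
#' Canonical interchange is a TSV with an `id` column and one column per
#' SNP (cells 0/1/2 or NA).  PLINK-RAW (`.raw`, as written by
#' `plink --recode A`) and VCF (GT field only; biallelic records;
#' multiallelic records are skipped with a warning) are import dialects.
#' VCF genotypes are oriented to minor-allele counts.
#'
#' @param path file path.
#' @param format `"tsv"`, `"plink_raw"` or `"vcf"`.
#' @return numeric matrix, individuals x SNPs, NA for missing.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
    ids <- as.character(d[[1]])
    M <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- ids
    check_geno_range(M, path)
    M
  } else if (format == "plink_raw") {
    d <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    keep <- setdiff(names(d), meta)
    M <- as.matrix(d[, keep, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- as.character(d$IID)
    colnames(M) <- sub("_[ACGT0-9]+$", "", keep)
    check_geno_range(M, path)
    M
  } else {
    read_genotypes_vcf(path)
  }
}

check_geno_range <- function(M, path) {
  bad <- !is.na(M) & !(M %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed genotype in ", path, " at row ", idx[1],
         ", column ", idx[2], ": values must be 0/1/2/NA")
  }
  invisible(M)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(is.na(x) | grepl("\\.", x),
           NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"),
                  numeric(1)))
  }
  M <- apply(gt, 2, count_alt)
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(rownames(gt), colnames(gt)))
  M <- t(M)
  colnames(M) <- rownames(gt)
  # orient to minor allele
  p <- colMeans(M, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  M[, flip] <- 2 - M[, flip]
  M
}

#' Write a genotype matrix as the canonical TSV
#'
#' @param genotypes matrix (0/1/2/NA) with rownames.
#' @param path output path.
#' @param provenance optional named character vector written as `#` header
#'   comments.
#' @export
write_genotypes <- function(genotypes, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_provenance(con, provenance)
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}

write_provenance <- function(con, provenance) {
  if (!is.null(provenance)) {
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  }
}

#' Write / read a simulated trial
#'
#' Persists the pedigree (CSV), genotype matrix (TSV), phenotypes (CSV)
#' and truth set (JSON) of a [simulate_trial()] result.
#'
#' @param sim result of [simulate_trial()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_trial <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(seed = sim$config$seed,
            package = as.character(utils::packageVersion("sprucegs")))
  ped_path <- file.path(dir, "pedigree.csv")
  con <- file(ped_path, "w"); write_provenance(con, prov)
  write.table(sim$pedigree, con, sep = ",", quote = FALSE,
              row.names = FALSE, na = "")
  close(con)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"), prov)
  ph_path <- file.path(dir, "phenotypes.csv")
  con <- file(ph_path, "w"); write_provenance(con, prov)
  write.table(sim$phenotypes, con, sep = ",", quote = FALSE,
              row.names = FALSE, na = "")
  close(con)
  truth <- sim$truth
  truth$true_breeding_values <- as.data.frame(truth$true_breeding_values)
  truth$true_dominance_deviations <-
    as.data.frame(truth$true_dominance_deviations)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a pedigree CSV
#' @param path file path (columns `id`, `sire`, `dam`, ...).
#' @return pedigree data frame (empty parent fields become `NA`).
#' @export
read_pedigree <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                  stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_pedigree(d)
}

#' Read a phenotype CSV
#' @param path file path (columns `tree`, `family`, `site`, `test`,
#'   `age`, trait columns).
#' @return data frame.
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = ",", comment.char = "#",
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' End-to-end pipeline on a synthetic or loaded trial
#'
#' Runs simulate/read, SNP QC + imputation, relationship matrices,
#' univariate REML fits (pedigree and genomic, additive and
#' additive-dominance), optional cross-validation, and top-fraction
#' selection with expected gains, writing every table with a provenance
#' header into a fresh run directory.
#'
#' @param config list; see Details.  Minimal usage:
#'   `run_pipeline(list(sim = sim_config(...), out_dir = tempfile()))`.
#' @details Recognised entries: `sim` (a [sim_config()]) or `paths`
#'   (list with `pedigree`, `genotypes`, `phenotypes`); `thresholds`
#'   ([qc_thresholds()]); `traits` (character subset to analyse; default
#'   first trait); `cv` (`list(k, reps)` or `NULL` to skip);
#'   `selection` (`list(intensity)` or `NULL` to skip); `out_dir`.
#' @return invisibly, a list with the run artefacts (`qc`, `fits`,
#'   `heritability`, `cv`, `selection`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% tempfile("sprucegs_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$sim)) {
    sim <- simulate_trial(config$sim)
    seed <- config$sim$seed
  } else if (!is.null(config$paths)) {
    sim <- list(pedigree = read_pedigree(config$paths$pedigree),
                genotypes = read_genotypes(config$paths$genotypes),
                phenotypes = read_phenotypes(config$paths$phenotypes))
    seed <- config$seed %||% 1L
  } else {
    stop("config needs either 'sim' or 'paths'")
  }
  prov <- c(seed = seed,
            package = as.character(utils::packageVersion("sprucegs")))
  traits <- config$traits %||% setdiff(colnames(sim$phenotypes),
                                       c("tree", "family", "site", "test",
                                         "age"))[1]
  unknown <- setdiff(traits, colnames(sim$phenotypes))
  if (length(unknown)) {
    stop("unknown trait(s) in config: ", paste(unknown, collapse = ", "))
  }
  # --- QC + imputation ---
  stats <- compute_snp_stats(sim$genotypes, sim$pedigree)
  flt <- filter_snps(stats, config$thresholds %||% qc_thresholds())
  G_raw <- sim$genotypes[, flt$retained, drop = FALSE]
  G_cmp <- impute_ldknni(G_raw, l = config$l %||% 30, k = config$k %||% 5)
  write_tbl(stats, file.path(out_dir, "snp_stats.tsv"), prov)
  write_tbl(data.frame(filter = names(flt$attrition),
                       removed = flt$attrition),
            file.path(out_dir, "snp_attrition.tsv"), prov)
  # --- relationship matrices ---
  A <- pedigree_to_A(sim$pedigree)
  G <- condition_psd(vanraden_G(G_cmp))
  D <- condition_psd(vitezica_D(G_cmp))
  # --- model fits ---
  sqrt_traits <- config$sqrt_traits %||% intersect(c("PICEOL", "PUNGENOL"),
                                                   traits)
  fits <- list()
  herit <- list()
  for (tr in traits) {
    trans <- if (tr %in% sqrt_traits) "sqrt" else "none"
    fits[[tr]] <- list(
      ablup_a = fit_univariate(sim$phenotypes, A, tr, transform = trans),
      gblup_a = fit_univariate(sim$phenotypes, G, tr, transform = trans),
      gblup_ad = fit_univariate(sim$phenotypes, G, tr, dominance = D,
                                transform = trans))
    herit[[tr]] <- data.frame(
      trait = tr,
      model = c("ablup_a", "gblup_a", "gblup_ad"),
      do.call(rbind, lapply(fits[[tr]], function(f) {
        h <- heritability(f)
        data.frame(h2 = h$h2, se_h2 = h$se_h2, d2 = h$d2, H2 = h$H2)
      })))
  }
  herit_tbl <- do.call(rbind, herit)
  write_tbl(herit_tbl, file.path(out_dir, "heritability.tsv"), prov)
  for (tr in traits) {
    ebv_tbl <- data.frame(id = names(fits[[tr]]$gblup_a$ebv),
                          gebv = unname(fits[[tr]]$gblup_a$ebv))
    write_tbl(ebv_tbl, file.path(out_dir, paste0("gebv_", tr, ".tsv")),
              prov)
  }
  # --- cross-validation ---
  cv_res <- NULL
  if (!is.null(config$cv)) {
    plan <- make_folds(sim$phenotypes, k = config$cv$k %||% 10,
                       reps = config$cv$reps %||% 10, seed = seed)
    cv_res <- lapply(traits, function(tr) {
      trans <- if (tr %in% sqrt_traits) "sqrt" else "none"
      run_cv(sim$phenotypes, tr, plan, K = G, transform = trans)
    })
    names(cv_res) <- traits
    cv_tbl <- do.call(rbind, lapply(traits, function(tr) {
      s <- cv_res[[tr]]$summary
      data.frame(trait = tr, metric = rownames(s), s, row.names = NULL)
    }))
    write_tbl(cv_tbl, file.path(out_dir, "cv_summary.tsv"), prov)
  }
  # --- selection ---
  sel_res <- NULL
  if (!is.null(config$selection)) {
    vals <- vapply(traits, function(tr) fits[[tr]]$gblup_a$ebv,
                   numeric(length(G$ids)))
    rownames(vals) <- G$ids
    prog <- sim$pedigree[sim$pedigree$cohort == "progeny", ]
    cand_ids <- intersect(G$ids, prog$id)
    means <- vapply(traits, function(tr) {
      trans <- if (tr %in% sqrt_traits) sqrt(sim$phenotypes[[tr]])
               else sim$phenotypes[[tr]]
      mean(trans, na.rm = TRUE)
    }, numeric(1))
    cands <- candidate_set(vals[cand_ids, , drop = FALSE], means,
                           setNames(prog$family, prog$id)[cand_ids])
    sel_res <- lapply(traits, function(tr) {
      sel <- select_top(setNames(cands$values[, tr], cands$ids),
                        config$selection$intensity %||% 0.05)
      expected_gains(sel, cands, strategy = paste0("top_", tr))
    })
    names(sel_res) <- traits
    gain_tbl <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(selected_on = tr, trait = names(sel_res[[tr]]$gains),
                 gain_pct = unname(sel_res[[tr]]$gains),
                 n_families = sel_res[[tr]]$n_families)
    }))
    write_tbl(gain_tbl, file.path(out_dir, "selection_gains.tsv"), prov)
  }
  invisible(list(qc = list(stats = stats, filter = flt),
                 kinship = list(A = A, G = G, D = D),
                 fits = fits, heritability = herit_tbl, cv = cv_res,
                 selection = sel_res, out_dir = out_dir))
}

write_tbl <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_provenance(con, provenance)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
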