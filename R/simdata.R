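# Synthetic breeding-trial generator.
#
# Emulates a multi-site full-sib progeny trial of the white-spruce type:
# two parental pools crossed into full-sib families, families planted on
# one or two of several sites with a single test per site, tree age as a
# covariate, SNP genotypes with block LD, and traits with additive,
# dominance, site, test and site-heterogeneous residual components.  The
# generator also returns the simulated truth (breeding values, dominance
# deviations, realized heritabilities and genetic correlations) so that
# estimation can be checked against it.

#' Trait specification for the trial generator
#'
#' All quantities are on the analysis scale (the scale the mixed models
#' see).  Right-skewed metabolite-like traits use `skew_transform =
#' "square"`: the generator emits the squared latent value, so the
#' analysis-side square-root transform returns to the scale simulated here.
#'
#' @param name trait label.
#' @param mean trait mean on the analysis scale.
#' @param phen_sd phenotypic standard deviation on the analysis scale,
#'   excluding site/test/age fixed effects.
#' @param h2_target,d2_target narrow-sense and dominance fractions of the
#'   phenotypic variance (`h2_target + d2_target <= 1`).
#' @param site_effect_sd standard deviation of site effects (trait units);
#'   test-within-site effects use half this value.
#' @param age_slope fixed slope on tree age (units per year, centred).
#' @param skew_transform `"none"` or `"square"`.
#' @param residual_profile per-site multipliers of the residual variance
#'   (mean 1); recycled/normalized to the number of sites at simulation
#'   time.
#' @return object of class `trait_spec`.
#' @export
trait_spec <- function(name, mean, phen_sd, h2_target, d2_target = 0,
                       site_effect_sd = 0.3 * phen_sd, age_slope = 0,
                       skew_transform = c("none", "square"),
                       residual_profile = c(0.7, 0.85, 1, 1.15, 1.3)) {
  skew_transform <- match.arg(skew_transform)
  stopifnot(phen_sd > 0, h2_target >= 0, d2_target >= 0,
            h2_target + d2_target <= 1)
  structure(list(name = name, mean = mean, phen_sd = phen_sd,
                 h2_target = h2_target, d2_target = d2_target,
                 site_effect_sd = site_effect_sd, age_slope = age_slope,
                 skew_transform = skew_transform,
                 residual_profile = residual_profile),
            class = "trait_spec")
}

#' Default seven-trait roster
#'
#' Growth (height, diameter, volume), wood quality (acoustic velocity) and
#' needle acetophenone traits (piceol, pungenol on the square-root analysis
#' scale, picein) with heritability targets, dominance fractions and an
#' additive genetic correlation structure typical of advanced conifer
#' breeding populations.  The correlation matrix is lightly shrunk toward
#' the identity when needed so that it is positive definite.
#'
#' @return list with `specs` (list of [trait_spec()]) and `genetic_corr`.
#' @export
default_trait_specs <- function() {
  specs <- list(
    trait_spec("HT", mean = 1119, phen_sd = 180, h2_target = 0.25,
               d2_target = 0.14, site_effect_sd = 90, age_slope = 25),
    trait_spec("DBH", mean = 155, phen_sd = 30, h2_target = 0.13,
               d2_target = 0.10, site_effect_sd = 12, age_slope = 3),
    trait_spec("VOL", mean = 10.5, phen_sd = 4.8, h2_target = 0.13,
               d2_target = 0.12, site_effect_sd = 1.8, age_slope = 0.5),
    trait_spec("VELO", mean = 3.53, phen_sd = 0.37, h2_target = 0.41,
               d2_target = 0.14, site_effect_sd = 0.1, age_slope = 0.01),
    trait_spec("PICEOL", mean = 2.45, phen_sd = 0.95, h2_target = 0.43,
               d2_target = 0.05, site_effect_sd = 0.25,
               skew_transform = "square"),
    trait_spec("PUNGENOL", mean = 2.1, phen_sd = 1.05, h2_target = 0.57,
               d2_target = 0.08, site_effect_sd = 0.25,
               skew_transform = "square"),
    trait_spec("PICEIN", mean = 12.1, phen_sd = 5.0, h2_target = 0.64,
               d2_target = 0, site_effect_sd = 1.5)
  )
  traits <- vapply(specs, `[[`, character(1), "name")
  R <- diag(7)
  dimnames(R) <- list(traits, traits)
  lower <- rbind(
    c("DBH", "HT", 0.44),
    c("VOL", "HT", 0.66), c("VOL", "DBH", 0.83),
    c("VELO", "HT", 0.06), c("VELO", "DBH", 0.03), c("VELO", "VOL", -0.04),
    c("PICEOL", "HT", -0.38), c("PICEOL", "DBH", -0.25),
    c("PICEOL", "VOL", -0.24), c("PICEOL", "VELO", -0.20),
    c("PUNGENOL", "HT", -0.14), c("PUNGENOL", "DBH", 0.07),
    c("PUNGENOL", "VOL", 0.06), c("PUNGENOL", "VELO", -0.04),
    c("PUNGENOL", "PICEOL", 0.60),
    c("PICEIN", "HT", -0.11), c("PICEIN", "DBH", -0.21),
    c("PICEIN", "VOL", -0.23), c("PICEIN", "VELO", -0.20),
    c("PICEIN", "PICEOL", -0.03), c("PICEIN", "PUNGENOL", -0.65)
  )
  for (i in seq_len(nrow(lower))) {
    R[lower[i, 1], lower[i, 2]] <- R[lower[i, 2], lower[i, 1]] <-
      as.numeric(lower[i, 3])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {
    lam <- (1e-6 - min(ev)) / (1 - min(ev))
    R <- (1 - lam) * R + lam * diag(7)
    dimnames(R) <- list(traits, traits)
  }
  list(specs = specs, genetic_corr = R)
}

#' Configuration of a synthetic breeding trial
#'
#' Defaults reproduce the scale and structure of a large multi-site white
#' spruce progeny trial: 120 female x 118 male parents, 136 full-sib
#' families of about ten phenotyped trees, an extra genotyped-only cohort,
#' five sites with tests nested in site, tree ages 16-28 used as a
#' covariate, and about 4,148 SNPs in LD blocks with low missingness.
#'
#' @param n_females,n_males numbers of founder parents.
#' @param n_families number of distinct (dam, sire) full-sib families
#'   (must not exceed `n_females * n_males`).
#' @param progeny_per_family phenotyped progeny per family.
#' @param n_unphenotyped extra genotyped-only progeny (spread over random
#'   families).
#' @param n_sites,tests_per_site trial layout; each family is planted on
#'   one or two sites and appears in a single test per site.
#' @param prop_single_site fraction of families present on one site only.
#' @param age_range inclusive range of tree ages (years), one age per test.
#' @param n_snps,maf_range,ld_block_size,ld_rho marker panel: founder
#'   minor-allele frequencies are uniform on `maf_range` (a subset of
#'   (0, 0.5]); SNPs within a block share a latent Gaussian factor with
#'   loading `sqrt(ld_rho)`.
#' @param missing_rate,genotyping_error_rate masking and error rates
#'   applied to the emitted genotype matrix (the truth is retained).
#' @param trait_specs list of [trait_spec()]; defaults to
#'   [default_trait_specs()].
#' @param genetic_corr additive genetic correlation matrix across traits
#'   (positive semi-definite).
#' @param seed integer seed controlling the whole trial.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_females = 120, n_males = 118, n_families = 136,
                       progeny_per_family = 10, n_unphenotyped = 206,
                       n_sites = 5, tests_per_site = 4,
                       prop_single_site = 0.2,
                       age_range = c(16, 28),
                       n_snps = 4148, maf_range = c(0.05, 0.5),
                       ld_block_size = 20, ld_rho = 0.8,
                       missing_rate = 0.002,
                       genotyping_error_rate = 2e-4,
                       trait_specs = NULL, genetic_corr = NULL,
                       seed = 1L) {
  if (is.null(trait_specs)) {
    def <- default_trait_specs()
    trait_specs <- def$specs
    if (is.null(genetic_corr)) genetic_corr <- def$genetic_corr
  }
  if (is.null(genetic_corr)) genetic_corr <- diag(length(trait_specs))
  counts <- c(n_females = n_females, n_males = n_males,
              n_families = n_families,
              progeny_per_family = progeny_per_family,
              n_sites = n_sites, tests_per_site = tests_per_site,
              n_snps = n_snps, ld_block_size = ld_block_size)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_unphenotyped < 0) stop("n_unphenotyped must be >= 0")
  if (n_families > n_females * n_males) {
    stop("infeasible design: n_families exceeds n_females * n_males")
  }
  rates <- c(missing_rate, genotyping_error_rate, prop_single_site)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must be a subset of (0, 0.5]")
  }
  nt <- length(trait_specs)
  stopifnot(is.matrix(genetic_corr), nrow(genetic_corr) == nt,
            ncol(genetic_corr) == nt)
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("genetic_corr is not positive semi-definite")
  }
  structure(list(n_females = n_females, n_males = n_males,
                 n_families = n_families,
                 progeny_per_family = progeny_per_family,
                 n_unphenotyped = n_unphenotyped, n_sites = n_sites,
                 tests_per_site = tests_per_site,
                 prop_single_site = prop_single_site,
                 age_range = age_range, n_snps = n_snps,
                 maf_range = maf_range, ld_block_size = ld_block_size,
                 ld_rho = ld_rho, missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 trait_specs = trait_specs, genetic_corr = genetic_corr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate the mating design and pedigree
#'
#' Founders are unrelated with unknown parents; each family is a distinct
#' (dam, sire) pair; each family contributes `progeny_per_family`
#' phenotyped progeny, and `n_unphenotyped` extra genotyped-only progeny
#' are assigned to random families.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `id`, `sire`, `dam`, `sex`, `cohort`,
#'   `family`, `phenotyped`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 11L, {
    females <- sprintf("F%03d", seq_len(config$n_females))
    males <- sprintf("M%03d", seq_len(config$n_males))
    pair_idx <- sample.int(config$n_females * config$n_males,
                           config$n_families)
    dam_i <- ((pair_idx - 1L) %% config$n_females) + 1L
    sire_i <- ((pair_idx - 1L) %/% config$n_females) + 1L
    fam_ids <- sprintf("fam%03d", seq_len(config$n_families))
    n_core <- config$n_families * config$progeny_per_family
    fam_of_core <- rep(seq_len(config$n_families),
                       each = config$progeny_per_family)
    fam_of_extra <- if (config$n_unphenotyped > 0) {
      sample(seq_len(config$n_families), config$n_unphenotyped,
             replace = TRUE)
    } else integer(0)
    fam_all <- c(fam_of_core, fam_of_extra)
    prog_ids <- sprintf("P%05d", seq_along(fam_all))
    founders <- data.frame(
      id = c(females, males),
      sire = NA_character_, dam = NA_character_,
      sex = rep(c("F", "M"), c(config$n_females, config$n_males)),
      cohort = "founder", family = NA_character_, phenotyped = FALSE,
      stringsAsFactors = FALSE)
    progeny <- data.frame(
      id = prog_ids,
      sire = males[sire_i[fam_all]],
      dam = females[dam_i[fam_all]],
      sex = NA_character_,
      cohort = "progeny",
      family = fam_ids[fam_all],
      phenotyped = c(rep(TRUE, n_core),
                     rep(FALSE, config$n_unphenotyped)),
      stringsAsFactors = FALSE)
    rbind(founders, progeny)
  })
}

#' Simulate SNP genotypes by gene drop
#'
#' Founder haplotypes are drawn from a block copula: SNPs inside a block of
#' `ld_block_size` share a latent Gaussian factor, so adjacent markers are
#' in LD while blocks are independent.  Progeny inherit one parental
#' haplotype per block (no within-block recombination, free recombination
#' between blocks).  Genotyping errors and missingness are injected at the
#' configured rates; the pre-masking matrix is kept in the `"truth"`
#' attribute together with founder allele frequencies in `"founder_p"`.
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return integer matrix (individuals x SNPs) of minor-allele counts with
#'   `NA` for missing calls.
#' @export
simulate_genotypes <- function(pedigree, config) {
  ped <- validate_pedigree(pedigree)
  with_seed(config$seed + 23L, {
    m <- config$n_snps
    b <- config$ld_block_size
    nblock <- ceiling(m / b)
    block_of <- rep(seq_len(nblock), each = b)[seq_len(m)]
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    thr <- qnorm(p)
    is_founder <- is.na(ped$sire) & is.na(ped$dam)
    founder_ids <- ped$id[is_founder]
    nf <- length(founder_ids)
    draw_haps <- function(nhap) {
      zb <- matrix(rnorm(nhap * nblock), nhap, nblock)
      lat <- sqrt(config$ld_rho) * zb[, block_of, drop = FALSE] +
        sqrt(1 - config$ld_rho) * matrix(rnorm(nhap * m), nhap, m)
      (lat < matrix(thr, nhap, m, byrow = TRUE)) + 0L
    }
    H1 <- matrix(0L, nrow(ped), m, dimnames = list(ped$id, NULL))
    H2 <- H1
    H1[founder_ids, ] <- draw_haps(nf)
    H2[founder_ids, ] <- draw_haps(nf)
    gamete <- function(parent) {
      pick <- rep(rbinom(nblock, 1, 0.5), each = b)[seq_len(m)]
      ifelse(pick == 1L, H1[parent, ], H2[parent, ])
    }
    ord <- pedigree_topological_order(ped)
    for (i in ord) {
      if (is_founder[i]) next
      H1[i, ] <- gamete(ped$sire[i])
      H2[i, ] <- gamete(ped$dam[i])
    }
    G <- H1 + H2
    colnames(G) <- sprintf("snp%05d", seq_len(m))
    truth <- G
    if (config$genotyping_error_rate > 0) {
      err <- which(runif(length(G)) < config$genotyping_error_rate)
      if (length(err)) {
        G[err] <- (G[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
      }
    }
    if (config$missing_rate > 0) {
      mis <- which(runif(length(G)) < config$missing_rate)
      G[mis] <- NA_integer_
    }
    attr(G, "truth") <- truth
    attr(G, "founder_p") <- p
    G
  })
}

#' Simulate phenotypes and the associated truth set
#'
#' Breeding values have covariance `genetic_corr (x) A`: when the
#' simulated genotypes are supplied they are built by a polygenic
#' gene-drop (every SNP carries a small normal effect, correlated across
#' traits, scaled so the realized additive variance among phenotyped
#' progeny matches the target), which makes the realized relationships
#' carry the additive signal exactly as marker-based models assume;
#' without genotypes they are drawn from the Cholesky factor of the
#' pedigree relationship matrix.  Dominance is a full-sib family effect (variance `sigma_d^2 / 4`, the
#' `4 sigma_f^2` convention) plus an individual deviation
#' (`3 sigma_d^2 / 4`), both sharing the trait correlation structure.
#' Phenotype = mean + site + test-within-site + age slope + a + d +
#' site-specific residual; traits with `skew_transform = "square"` emit the
#' squared latent value.  Families are placed on one or two sites with a
#' single test per site, reproducing the family-site confounding of real
#' multi-site trials.
#'
#' @inheritParams simulate_genotypes
#' @param genotypes optional output of [simulate_genotypes()] (its pre-
#'   masking truth matrix is used for the polygenic gene-drop).
#' @return list with `phenotypes` (data frame: `tree`, `family`, `site`,
#'   `test`, `age`, one column per trait) and `truth` (list:
#'   `true_breeding_values`, `true_dominance_deviations`, `realized_h2`,
#'   `realized_ra`, trait means/sds on the analysis scale).
#' @export
simulate_traits <- function(pedigree, config, genotypes = NULL) {
  ped <- validate_pedigree(pedigree)
  specs <- config$trait_specs
  nt <- length(specs)
  traits <- vapply(specs, `[[`, character(1), "name")
  Rg <- config$genetic_corr
  ev <- eigen(Rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("genetic_corr is not positive semi-definite")
  Rchol <- chol(Rg + diag(1e-10, nt))
  with_seed(config$seed + 37L, {
    ids <- ped$id
    n <- length(ids)
    sig_p <- vapply(specs, `[[`, numeric(1), "phen_sd")
    sig_a <- sig_p * sqrt(vapply(specs, `[[`, numeric(1), "h2_target"))
    sig_d <- sig_p * sqrt(vapply(specs, `[[`, numeric(1), "d2_target"))
    pheno_ids <- ped$id[ped$phenotyped]
    if (!is.null(genotypes)) {
      Z <- attr(genotypes, "truth")
      if (is.null(Z)) Z <- genotypes
      Z <- Z[ids, , drop = FALSE]
      storage.mode(Z) <- "double"
      eff <- matrix(rnorm(ncol(Z) * nt), ncol(Z), nt) %*% Rchol
      BV <- Z %*% eff
      BV <- scale(BV, center = TRUE, scale = FALSE)
      sd_prog <- apply(BV[pheno_ids, , drop = FALSE], 2, sd)
      BV <- sweep(BV, 2, ifelse(sig_a > 0, sd_prog / sig_a, 1), "/")
      BV[, sig_a == 0] <- 0
    } else {
      A <- pedigree_to_A(ped)
      ids <- A$ids
      La <- t(chol(A$values + diag(1e-10, n)))
      BV <- La %*% matrix(rnorm(n * nt), n, nt) %*% Rchol
      BV <- sweep(BV, 2, sig_a, "*")
    }
    dimnames(BV) <- list(ids, traits)
    fam_ids <- sort(unique(ped$family[!is.na(ped$family)]))
    FAME <- matrix(rnorm(length(fam_ids) * nt), length(fam_ids), nt) %*% Rchol
    FAME <- sweep(FAME, 2, sig_d / 2, "*")  # var sigma_d^2/4
    rownames(FAME) <- fam_ids
    DEV <- matrix(rnorm(n * nt), n, nt) %*% Rchol
    DEV <- sweep(DEV, 2, sig_d * sqrt(3) / 2, "*")  # var 3 sigma_d^2/4
    dimnames(DEV) <- list(ids, traits)
    DOM <- DEV
    has_fam <- !is.na(ped$family)
    DOM[ped$id[has_fam], ] <- DOM[ped$id[has_fam], , drop = FALSE] +
      FAME[ped$family[has_fam], , drop = FALSE]
    # trial layout
    nfam <- length(fam_ids)
    single <- runif(nfam) < config$prop_single_site
    fam_sites <- lapply(seq_len(nfam), function(i) {
      k <- if (single[i] || config$n_sites == 1) 1 else 2
      sample.int(config$n_sites, k)
    })
    fam_test <- lapply(fam_sites, function(ss) {
      setNames(sample.int(config$tests_per_site, length(ss),
                          replace = TRUE), ss)
    })
    test_age <- matrix(sample(seq(config$age_range[1], config$age_range[2]),
                              config$n_sites * config$tests_per_site,
                              replace = TRUE),
                       config$n_sites, config$tests_per_site)
    prog <- ped[ped$phenotyped, ]
    fam_index <- match(prog$family, fam_ids)
    site_of <- integer(nrow(prog))
    for (i in seq_len(nfam)) {
      rows <- which(fam_index == i)
      ss <- fam_sites[[i]]
      site_of[rows] <- ss[1 + (sample(seq_along(rows)) %% length(ss))]
    }
    test_of <- vapply(seq_len(nrow(prog)), function(r) {
      fam_test[[fam_index[r]]][[as.character(site_of[r])]]
    }, integer(1))
    age_of <- test_age[cbind(site_of, test_of)]
    site_eff <- matrix(rnorm(config$n_sites * nt), config$n_sites, nt)
    site_eff <- sweep(site_eff, 2,
                      vapply(specs, `[[`, numeric(1), "site_effect_sd"), "*")
    test_eff <- array(rnorm(config$n_sites * config$tests_per_site * nt),
                      c(config$n_sites, config$tests_per_site, nt))
    for (t in seq_len(nt)) {
      test_eff[, , t] <- test_eff[, , t] * specs[[t]]$site_effect_sd / 2
    }
    mid_age <- mean(config$age_range)
    pheno <- data.frame(tree = prog$id, family = prog$family,
                        site = sprintf("S%d", site_of),
                        test = sprintf("T%d", test_of),
                        age = age_of, stringsAsFactors = FALSE)
    resid_mat <- matrix(NA_real_, nrow(prog), nt)
    for (t in seq_len(nt)) {
      sp <- specs[[t]]
      prof <- rep_len(sp$residual_profile, config$n_sites)
      prof <- prof / mean(prof)
      ve <- (1 - sp$h2_target - sp$d2_target) * sp$phen_sd^2
      sd_site <- sqrt(ve * prof)
      e <- rnorm(nrow(prog), 0, sd_site[site_of])
      resid_mat[, t] <- e
      lat <- sp$mean + site_eff[site_of, t] +
        test_eff[cbind(site_of, test_of, t)] +
        sp$age_slope * (age_of - mid_age) +
        BV[prog$id, t] + DOM[prog$id, t] + e
      pheno[[sp$name]] <- if (sp$skew_transform == "square") lat^2 else lat
    }
    va <- apply(BV[prog$id, , drop = FALSE], 2, var)
    vd <- apply(DOM[prog$id, , drop = FALSE], 2, var)
    ve_r <- apply(resid_mat, 2, var)
    truth <- list(
      true_breeding_values = BV,
      true_dominance_deviations = DOM,
      realized_h2 = setNames(va / (va + vd + ve_r), traits),
      realized_ra = cor(BV[prog$id, , drop = FALSE]),
      trait_means = setNames(vapply(specs, `[[`, numeric(1), "mean"),
                             traits),
      sigma_a = setNames(sig_a, traits),
      sigma_d = setNames(sig_d, traits))
    list(phenotypes = pheno, truth = truth)
  })
}

#' Simulate a complete trial
#'
#' Convenience wrapper: pedigree, genotypes and phenotypes/truth from one
#' configuration, fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `truth`,
#'   `config`.
#' @export
simulate_trial <- function(config) {
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  tr <- simulate_traits(ped, config, genotypes = gen)
  list(pedigree = ped, genotypes = gen, phenotypes = tr$phenotypes,
       truth = tr$truth, config = config)
}
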