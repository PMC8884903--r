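#' Configuration for the pooled in vivo screen simulator
#'
#' Defaults describe a desk-scale screen: a 1000-gene knockout library with 6
#' guides per gene, 8 mice, the 5 metastatic target organs, an implantation
#' bottleneck of 1e5 cells, 1e6 reads per sequenced sample, and 20 planted
#' metastasis suppressors (10 seeding every organ, 10 organ-specific) whose
#' knockout raises organ-seeding hazard 100-fold over a baseline per-cell
#' seeding probability of 1e-6.
#'
#' @param n_genes Number of genes in the library.
#' @param sgrnas_per_gene Guides per gene (GeCKO-style, default 6).
#' @param n_mice Number of implanted mice.
#' @param organs Metastatic organ classes.
#' @param cells_implanted Implantation bottleneck size (cells per fat pad).
#' @param moi Library infection multiplicity (recorded provenance; the
#'   combined infection/selection loss is `dropout_frac`).
#' @param selection_days Puromycin selection length, days (recorded
#'   provenance).
#' @param dropout_frac Per-sgRNA probability of loss during infection at low
#'   MOI plus selection.
#' @param expansion Neutral expansion factor of the primary tumor relative to
#'   the implanted bolus, applied before dissemination.
#' @param p0 Baseline per-cell per-organ seeding probability.
#' @param h Hazard multiplier (>= 1) for planted suppressor knockouts.
#' @param n_planted_pan Planted suppressors active in every organ.
#' @param n_planted_single Planted suppressors active in a single organ each
#'   (assigned round-robin over `organs`).
#' @param reads_per_sample Sequencing depth per sample.
#' @param alpha_od Dirichlet-multinomial concentration (smaller = more
#'   overdispersed sequencing).
#' @param sigma Log-normal SD of founder sgRNA abundance.
#' @param clone_sigma Log-normal SD of per-clone expansion in lesions.
#' @param blood_primary_frac Fraction of blood sample composition drawn from
#'   the primary tumor (the rest from pooled disseminating clones).
#' @param seed Master RNG seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 1000L, sgrnas_per_gene = 6L,
                              n_mice = 8L,
                              organs = c("lung", "liver", "spleen", "brain", "kidney"),
                              cells_implanted = 1e5, moi = 0.1,
                              selection_days = 7L, dropout_frac = 0.05,
                              expansion = 150, p0 = 1e-6, h = 100,
                              n_planted_pan = 10L, n_planted_single = 10L,
                              reads_per_sample = 1e6, alpha_od = 100,
                              sigma = 0.5, clone_sigma = 1,
                              blood_primary_frac = 0.9, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              sgrnas_per_gene = as.integer(sgrnas_per_gene),
              n_mice = as.integer(n_mice), organs = organs,
              cells_implanted = cells_implanted, moi = moi,
              selection_days = as.integer(selection_days),
              dropout_frac = dropout_frac, expansion = expansion,
              p0 = p0, h = h,
              n_planted_pan = as.integer(n_planted_pan),
              n_planted_single = as.integer(n_planted_single),
              reads_per_sample = reads_per_sample, alpha_od = alpha_od,
              sigma = sigma, clone_sigma = clone_sigma,
              blood_primary_frac = blood_primary_frac,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, cfg$sgrnas_per_gene >= 1L, cfg$n_mice >= 1L,
            length(cfg$organs) >= 1L, cfg$cells_implanted >= 1,
            cfg$dropout_frac >= 0, cfg$dropout_frac < 1,
            cfg$expansion > 0, cfg$p0 >= 0, cfg$h >= 1,
            cfg$n_planted_pan + cfg$n_planted_single <= cfg$n_genes,
            cfg$reads_per_sample >= 1, cfg$alpha_od > 0, cfg$sigma >= 0,
            cfg$clone_sigma >= 0,
            cfg$blood_primary_frac >= 0, cfg$blood_primary_frac <= 1)
  class(cfg) <- "screen_sim_config"
  cfg
}

# Dirichlet-multinomial draw: n reads over composition prop (sums to 1),
# concentration alpha. Zero composition gives a zero column.
.rdirmult <- function(n, prop, alpha) {
  if (sum(prop) == 0) return(integer(length(prop)))
  prop <- prop / sum(prop)
  g <- stats::rgamma(length(prop), shape = alpha * prop)
  if (sum(g) == 0) g[which.max(prop)] <- 1
  as.integer(stats::rmultinom(1L, n, g / sum(g)))
}

# sum of k iid lognormal(0, s) expansion factors per entry of `seeds`
.clone_expand <- function(seeds, s) {
  w <- numeric(length(seeds))
  nz <- which(seeds > 0L)
  for (i in nz) w[i] <- sum(stats::rlnorm(seeds[i], 0, s))
  w
}

#' Simulate a bottlenecked in vivo pooled knockout screen
#'
#' Generative stages, each with its own seed derived from the master seed:
#' (1) founder sgRNA abundances (log-normal) with random per-sgRNA dropout
#' from low-MOI infection and selection; (2) per mouse, a multinomial
#' implantation bottleneck of `cells_implanted` cells; (3) neutral primary
#' expansion and a second multinomial bottleneck for the recurrent tumor;
#' (4) dissemination: per mouse, organ and sgRNA clone, seeded-clone counts
#' are Poisson in (expanded clone size) x `p0` x the gene/organ hazard
#' multiplier, and lesion composition weights each seeded clone by a
#' log-normal expansion factor; (5) blood as a mixture of primary and pooled
#' disseminating clones; (6) Dirichlet-multinomial sequencing of every sample
#' at `reads_per_sample` reads. One preimplant sample is emitted, plus per
#' mouse one primary, one recurrent, one blood, and one metastasis sample per
#' organ (all-zero column when no clone seeded that organ).
#'
#' @param cfg A `screen_sim_config`.
#' @return List with `library` (`crispr_library`), `sheet` (`sample_sheet`),
#'   `counts` (sgRNA x sample integer matrix), and `truth` (planted genes,
#'   per-gene organ profile, config echo).
#' @export
simulate_screen <- function(cfg = screen_sim_config()) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  n_sg <- cfg$n_genes * cfg$sgrnas_per_gene
  if (n_sg < 1L) stop("config implies an empty library")
  if (cfg$reads_per_sample < 1) stop("config implies zero reads")

  set.seed(cfg$seed)
  stage_seed <- sample.int(.Machine$integer.max, 7L)

  # library design
  set.seed(stage_seed[1L])
  genes <- sprintf("Gene%04d", seq_len(cfg$n_genes))
  sg_gene <- rep(genes, each = cfg$sgrnas_per_gene)
  sg_id <- paste0(sg_gene, "_sg", seq_len(cfg$sgrnas_per_gene))
  spacers <- vapply(seq_len(n_sg), function(i) {
    paste0(sample(c("A", "C", "G", "T"), 20L, replace = TRUE), collapse = "")
  }, character(1))
  while (anyDuplicated(spacers)) {
    d <- which(duplicated(spacers))
    spacers[d] <- vapply(d, function(i) {
      paste0(sample(c("A", "C", "G", "T"), 20L, replace = TRUE), collapse = "")
    }, character(1))
  }
  lib <- new_library(data.frame(sgrna_id = sg_id, spacer = spacers,
                                gene = sg_gene, stringsAsFactors = FALSE))

  # planted effect profile
  planted_pan <- genes[seq_len(cfg$n_planted_pan)]
  planted_single <- genes[cfg$n_planted_pan + seq_len(cfg$n_planted_single)]
  single_organ <- if (cfg$n_planted_single > 0L) {
    structure(rep(cfg$organs, length.out = cfg$n_planted_single),
              names = planted_single)
  } else structure(character(0), names = character(0))
  h_of <- function(gene_vec, organ) {
    h <- rep(1, length(gene_vec))
    h[gene_vec %in% planted_pan] <- cfg$h
    sel <- names(single_organ)[single_organ == organ]
    h[gene_vec %in% sel] <- cfg$h
    h
  }

  # stage 1: founder abundance + dropout
  set.seed(stage_seed[2L])
  founder <- stats::rlnorm(n_sg, 0, cfg$sigma)
  founder[stats::runif(n_sg) < cfg$dropout_frac] <- 0
  if (sum(founder) == 0) stop("all sgRNAs lost at infection; lower dropout_frac")
  founder_prop <- founder / sum(founder)

  samples <- list(); meta <- list()
  add_sample <- function(id, compartment, organ, subject, week, prop, alpha) {
    samples[[id]] <<- .rdirmult(cfg$reads_per_sample, prop, alpha)
    meta[[id]] <<- data.frame(sample_id = id, compartment = compartment,
                              organ = organ, subject_id = subject,
                              week = week, stringsAsFactors = FALSE)
  }

  set.seed(stage_seed[3L])
  add_sample("preimplant", "preimplant", "", "pool", 0L,
             founder_prop, cfg$alpha_od)

  set.seed(stage_seed[4L])
  for (mi in seq_len(cfg$n_mice)) {
    mouse <- sprintf("mouse%02d", mi)
    # stage 2: implantation bottleneck
    implant <- as.integer(stats::rmultinom(1L, cfg$cells_implanted, founder_prop))
    primary_prop <- if (sum(implant) > 0) implant / sum(implant) else implant
    # stage 3: recurrent = second bottleneck of the primary
    recurrent <- as.integer(stats::rmultinom(1L, cfg$cells_implanted, primary_prop))
    recur_prop <- if (sum(recurrent) > 0) recurrent / sum(recurrent) else recurrent
    # stage 4: dissemination per organ
    expanded <- implant * cfg$expansion
    organ_comp <- matrix(0, n_sg, length(cfg$organs),
                         dimnames = list(NULL, cfg$organs))
    for (o in cfg$organs) {
      lam <- expanded * cfg$p0 * h_of(sg_gene, o)
      seeds <- stats::rpois(n_sg, lam)
      organ_comp[, o] <- .clone_expand(seeds, cfg$clone_sigma)
    }
    # stage 5: blood mixture
    pooled <- rowSums(organ_comp)
    blood_prop <- if (sum(pooled) > 0) {
      cfg$blood_primary_frac * primary_prop +
        (1 - cfg$blood_primary_frac) * pooled / sum(pooled)
    } else primary_prop

    week_blood <- 2L + (mi - 1L) %% 7L
    add_sample(paste0(mouse, "_primary"), "primary", "", mouse, 8L,
               primary_prop, cfg$alpha_od)
    add_sample(paste0(mouse, "_recurrent"), "recurrent", "", mouse, 8L,
               recur_prop, cfg$alpha_od)
    add_sample(paste0(mouse, "_blood"), "blood", "", mouse, week_blood,
               blood_prop, cfg$alpha_od)
    for (o in cfg$organs) {
      add_sample(paste0(mouse, "_met_", o), "metastasis", o, mouse, 8L,
                 organ_comp[, o], cfg$alpha_od)
    }
  }

  counts <- do.call(cbind, samples)
  rownames(counts) <- sg_id
  storage.mode(counts) <- "integer"
  sheet <- new_sample_sheet(do.call(rbind, meta))

  truth <- list(planted_pan = planted_pan,
                planted_single = planted_single,
                single_organ = as.list(single_organ),
                planted = c(planted_pan, planted_single),
                config = cfg)
  list(library = lib, sheet = sheet,
       counts = new_count_matrix(counts, lib, sheet), truth = truth)
}

#' Write simulated screen outputs as pipeline-ready files
#'
#' @param sim Result of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_screen_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(library = file.path(dir, "library.csv"),
             sheet = file.path(dir, "samples.tsv"),
             counts = file.path(dir, "counts.tsv"),
             truth = file.path(dir, "truth.json"))
  write_library(sim$library, paths[["library"]])
  write_sample_sheet(sim$sheet, paths[["sheet"]])
  write_counts(sim$counts, paths[["counts"]])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Configuration for the patient-cohort simulator
#'
#' Defaults describe a desk-scale cohort: 500 genes of which 50 are planted
#' suppressors, 200 tumor and 100 normal subjects, a 1.5-SD down-shift of
#' planted genes in tumors, a hazard ratio of 3 for the low-expression arm,
#' and 30% censoring. Planted genes share a latent per-tumor aggressiveness
#' factor (correlation `rho`), which is what gives each individual gene's
#' median split a marginal survival signal.
#'
#' @param n_genes Number of genes.
#' @param n_planted Number of planted suppressor genes.
#' @param n_tumor,n_normal Subjects per group.
#' @param delta Tumor down-shift of planted genes, in SD units.
#' @param hr Hazard ratio for the low arm of the planted-gene mean.
#' @param lambda Baseline exponential hazard (per unit time).
#' @param censor_frac Expected fraction of censored tumor subjects.
#' @param rho Correlation of planted-gene expression with the latent
#'   aggressiveness factor in tumors.
#' @param seed Master RNG seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_genes = 500L, n_planted = 50L,
                              n_tumor = 200L, n_normal = 100L,
                              delta = 1.5, hr = 3, lambda = 0.1,
                              censor_frac = 0.3, rho = 0.8, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_planted = as.integer(n_planted),
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              delta = delta, hr = hr, lambda = lambda,
              censor_frac = censor_frac, rho = rho, seed = as.integer(seed))
  stopifnot(cfg$n_planted <= cfg$n_genes, cfg$delta >= 0, cfg$hr >= 1,
            cfg$lambda > 0, cfg$censor_frac >= 0, cfg$censor_frac < 1,
            cfg$rho >= 0, cfg$rho <= 1, cfg$n_tumor >= 2L, cfg$n_normal >= 2L)
  class(cfg) <- "cohort_sim_config"
  cfg
}

#' Simulate a tumor/normal expression cohort with survival
#'
#' Expression is standard normal on the log scale per gene and subject.
#' Planted genes are shifted down by `delta` SD in tumors and loaded on a
#' shared latent aggressiveness factor with correlation `rho`. Survival times
#' for tumor subjects are exponential with hazard `lambda * hr^z`, where
#' `z = 1` for subjects in the low median-split arm of the planted-gene mean
#' expression. Censored subjects (probability `censor_frac`) have their time
#' replaced by a uniform fraction of the event time.
#'
#' @param cfg A `cohort_sim_config`.
#' @return List with `cohort` (a `cohort_data`) and `truth` (planted genes,
#'   config echo).
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)

  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  planted <- genes[seq_len(cfg$n_planted)]
  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(cfg$n_normal))

  n_subj <- cfg$n_tumor + cfg$n_normal
  expr <- matrix(stats::rnorm(cfg$n_genes * n_subj), cfg$n_genes, n_subj,
                 dimnames = list(genes, c(tumor_ids, normal_ids)))
  u <- stats::rnorm(cfg$n_tumor)  # latent aggressiveness per tumor
  if (cfg$n_planted > 0L) {
    eps <- matrix(stats::rnorm(cfg$n_planted * cfg$n_tumor),
                  cfg$n_planted, cfg$n_tumor)
    expr[planted, tumor_ids] <- -cfg$delta +
      cfg$rho * matrix(u, cfg$n_planted, cfg$n_tumor, byrow = TRUE) +
      sqrt(1 - cfg$rho^2) * eps
  }

  group <- structure(rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
                     names = c(tumor_ids, normal_ids))

  if (cfg$n_planted > 0L) {
    burden <- colMeans(expr[planted, tumor_ids, drop = FALSE])
    z <- as.integer(median_split(burden) == "low")
  } else z <- integer(cfg$n_tumor)
  time <- stats::rexp(cfg$n_tumor, rate = cfg$lambda * cfg$hr^z)
  event <- rep(1L, cfg$n_tumor)
  cens <- stats::runif(cfg$n_tumor) < cfg$censor_frac
  time[cens] <- time[cens] * stats::runif(sum(cens))
  event[cens] <- 0L
  surv <- data.frame(subject_id = tumor_ids, time = time, event = event,
                     stringsAsFactors = FALSE)

  list(cohort = cohort_data(expr, group, surv),
       truth = list(planted = planted, config = cfg))
}
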