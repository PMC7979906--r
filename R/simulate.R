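#' Simulation configuration
#'
#' Describes a synthetic SNP panel: several populations diverged from a
#' common ancestral pool under the Balding-Nichols model, optional admixed
#' individuals, clonal (graft) duplicates with genotyping error and allelic
#' dropout, and uniform per-call missingness. Every random draw is governed
#' by `seed`, so a config is a complete recipe for one dataset.
#'
#' @param pop_sizes named integer vector: individuals per population (names
#'   are the population labels).
#' @param divergence_F per-population drift parameter in \[0, 1), recycled if
#'   length 1. `F = 0` means the population keeps the ancestral frequencies.
#' @param n_sites number of SNP sites.
#' @param ancestral_maf_range interval within (0, 0.5\]; ancestral minor
#'   allele frequencies are uniform on it and the minor allele is attached
#'   to REF or ALT with equal probability (frequencies are unpolarised).
#' @param admixed list of admixed individuals, each a list with `id` and `q`
#'   (named ancestry proportions over population labels, summing to 1).
#' @param clone_pairs data.frame with columns `source`, `clone` (sample ids;
#'   the clone's drawn genotype is replaced by a perturbed copy of the
#'   source) and optionally `error_rate`, `dropout_rate` overriding the
#'   defaults below.
#' @param error_rate default per-call probability that a clone's genotype is
#'   replaced by one of the other two codes (symmetric genotyping error).
#' @param dropout_rate default per-call probability that a clone's
#'   heterozygous genotype collapses to a random homozygote (allelic
#'   dropout, the characteristic reduced-representation artifact).
#' @param missing_rate per-call missingness applied to every individual.
#' @param seed integer seed (mandatory).
#' @param sites_per_locus SNPs sharing one synthetic RAD locus id (default 2,
#'   so the one-SNP-per-locus filter has work to do).
#' @return a `sim_config` list.
#' @export
sim_config <- function(pop_sizes, divergence_F, n_sites,
                       ancestral_maf_range = c(0.05, 0.5),
                       admixed = list(), clone_pairs = NULL,
                       error_rate = 0.01, dropout_rate = 0.10,
                       missing_rate = 0.0, seed, sites_per_locus = 2L) {
  if (missing(seed)) abort("sim_config: seed is mandatory")
  if (is.null(names(pop_sizes))) names(pop_sizes) <- paste0("P", seq_along(pop_sizes))
  if (any(pop_sizes < 1)) abort("pop_sizes must all be >= 1")
  divergence_F <- rep_len(divergence_F, length(pop_sizes))
  if (any(divergence_F < 0 | divergence_F >= 1)) abort("divergence_F must be in [0, 1)")
  names(divergence_F) <- names(pop_sizes)
  if (ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2]) {
    abort("ancestral_maf_range must lie within (0, 0.5]")
  }
  for (ad in admixed) {
    if (is.null(ad$id) || is.null(ad$q)) abort("each admixed entry needs id and q")
    if (abs(sum(ad$q) - 1) > 1e-8) abort("ancestry proportions must sum to 1 (%s)", ad$id)
    if (!all(names(ad$q) %in% names(pop_sizes))) abort("unknown population in q for %s", ad$id)
  }
  rates <- c(error_rate, dropout_rate, missing_rate)
  if (any(rates < 0 | rates >= 1)) abort("rates must be in [0, 1)")
  if (!is.null(clone_pairs)) {
    clone_pairs <- as.data.frame(clone_pairs, stringsAsFactors = FALSE)
    if (!all(c("source", "clone") %in% names(clone_pairs))) {
      abort("clone_pairs needs columns source and clone")
    }
    if (is.null(clone_pairs$error_rate)) clone_pairs$error_rate <- error_rate
    if (is.null(clone_pairs$dropout_rate)) clone_pairs$dropout_rate <- dropout_rate
  }
  structure(list(pop_sizes = pop_sizes, divergence_F = divergence_F,
                 n_sites = as.integer(n_sites),
                 ancestral_maf_range = ancestral_maf_range,
                 admixed = admixed, clone_pairs = clone_pairs,
                 error_rate = error_rate, dropout_rate = dropout_rate,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 sites_per_locus = as.integer(sites_per_locus)),
            class = "sim_config")
}

#' Default desk-scale simulation preset
#'
#' A 90-individual, 4,000-site panel over eight populations (labelled
#' A1, A2, B, C, D, E, F, H after the field's usual group letters) emulating
#' a partly clonal orchard-and-wild collection: one 10-member graft lineage
#' (population A2 is a single founder plus nine clonal copies) and five
#' independent clone pairs placed in other populations, with symmetric
#' genotyping error 0.01, allelic dropout 0.10 on clone copies, and 10%
#' missing calls. Divergence parameters are spread over 0.08-0.25 so that
#' pairwise Fst spans the few-percent to ~0.3 range typical of diverged
#' local lineages.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
sim_preset_default <- function(seed = 20260101L) {
  pop_sizes <- c(A1 = 15, A2 = 10, B = 12, C = 12, D = 12, E = 10, F = 10, H = 9)
  divergence <- c(A1 = 0.08, A2 = 0.25, B = 0.15, C = 0.10,
                  D = 0.08, E = 0.12, F = 0.10, H = 0.20)
  # A2 is one graft lineage: nine clones of its first member.
  cluster <- data.frame(source = "A2_01",
                        clone = sprintf("A2_%02d", 2:10))
  pairs <- data.frame(source = c("F_01", "C_01", "B_01", "A1_01", "A1_03"),
                      clone  = c("F_02", "C_02", "B_02", "A1_02", "A1_04"))
  sim_config(pop_sizes = pop_sizes, divergence_F = divergence,
             n_sites = 4000L, clone_pairs = rbind(cluster, pairs),
             error_rate = 0.01, dropout_rate = 0.10, missing_rate = 0.10,
             seed = seed)
}

# ancestral frequency draw: uniform minor-allele frequency, random polarity
draw_ancestral_freq <- function(cfg) {
  u <- stats::runif(cfg$n_sites, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  flip <- stats::runif(cfg$n_sites) < 0.5
  ifelse(flip, 1 - u, u)
}

# Balding-Nichols draw given ancestral p and drift F (internal, no seeding)
draw_freqs_internal <- function(cfg) {
  p <- draw_ancestral_freq(cfg)
  freq <- matrix(NA_real_, nrow = length(cfg$pop_sizes), ncol = cfg$n_sites,
                 dimnames = list(names(cfg$pop_sizes), NULL))
  for (k in seq_along(cfg$pop_sizes)) {
    F <- cfg$divergence_F[k]
    freq[k, ] <- if (F == 0) p else
      stats::rbeta(cfg$n_sites, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  list(ancestral = p, freq = freq)
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' Ancestral ALT frequencies are uniform over the configured minor-allele
#' range (polarity random); each population's frequency is Beta-distributed
#' around the ancestral value with drift parameter `F`:
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. `F = 0` returns the ancestral frequency
#' unchanged. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `ancestral` (length `n_sites`) and `freq`
#'   (populations x sites matrix).
#' @export
draw_population_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  draw_freqs_internal(cfg)
}

# clone perturbation: allelic dropout (het -> random hom) then symmetric
# genotyping error (any code -> one of the other two), in that order
perturb_clone <- function(g, error_rate, dropout_rate) {
  n <- length(g)
  het <- which(!is.na(g) & g == 1L)
  if (length(het) && dropout_rate > 0) {
    drop <- het[stats::runif(length(het)) < dropout_rate]
    if (length(drop)) g[drop] <- sample(c(0L, 2L), length(drop), replace = TRUE)
  }
  if (error_rate > 0) {
    err <- which(!is.na(g) & stats::runif(n) < error_rate)
    if (length(err)) {
      shift <- sample(1:2, length(err), replace = TRUE)
      g[err] <- (g[err] + shift) %% 3L
    }
  }
  g
}

#' Simulate a truth-tracked genotype dataset
#'
#' Non-clonal individuals draw genotypes `Binomial(2, sum_k q_k p_kl)` per
#' site from their (possibly admixed) expected allele frequency. Clones copy
#' their source's pre-missingness genotypes and are then perturbed by
#' allelic dropout and symmetric genotyping error. Finally every call is set
#' missing independently with the configured rate. Sites are grouped into
#' synthetic RAD loci (`sites_per_locus` SNPs per locus id).
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (a `sim_truth`
#'   list: `samples` data.frame with `sample_id`, `population`, `kind`;
#'   `q_matrix` for admixed individuals; `clone_registry`; the realized
#'   per-population `freq` table; and the config).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fr <- draw_freqs_internal(cfg)

  labels <- rep(names(cfg$pop_sizes), cfg$pop_sizes)
  ids <- unlist(lapply(names(cfg$pop_sizes), function(p) {
    sprintf("%s_%02d", p, seq_len(cfg$pop_sizes[[p]]))
  }), use.names = FALSE)
  kind <- rep("member", length(ids))

  # expected per-individual ALT frequency at every site
  exp_freq <- fr$freq[labels, , drop = FALSE]
  if (length(cfg$admixed)) {
    qmat <- matrix(0, nrow = length(cfg$admixed), ncol = length(cfg$pop_sizes),
                   dimnames = list(vapply(cfg$admixed, `[[`, "", "id"),
                                   names(cfg$pop_sizes)))
    for (i in seq_along(cfg$admixed)) {
      qmat[i, names(cfg$admixed[[i]]$q)] <- cfg$admixed[[i]]$q
    }
    exp_freq <- rbind(exp_freq, qmat %*% fr$freq)
    ids <- c(ids, rownames(qmat))
    labels <- c(labels, rep("admixed", nrow(qmat)))
    kind <- c(kind, rep("admixed", nrow(qmat)))
  } else {
    qmat <- NULL
  }
  if (anyDuplicated(ids)) abort("duplicated simulated sample ids")

  n <- length(ids)
  calls <- matrix(stats::rbinom(n * cfg$n_sites, 2L, as.vector(exp_freq)),
                  nrow = n, dimnames = list(ids, NULL))

  registry <- cfg$clone_pairs
  if (!is.null(registry)) {
    unknown <- setdiff(c(registry$source, registry$clone), ids)
    if (length(unknown)) abort("clone_pairs names unknown sample(s): %s",
                               paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(registry))) {
      src <- registry$source[i]; cl <- registry$clone[i]
      calls[cl, ] <- perturb_clone(calls[src, ], registry$error_rate[i],
                                   registry$dropout_rate[i])
      kind[match(cl, ids)] <- "clone"
    }
  }

  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }

  n_loci <- ceiling(cfg$n_sites / cfg$sites_per_locus)
  locus <- sprintf("L%05d", rep(seq_len(n_loci), each = cfg$sites_per_locus))[seq_len(cfg$n_sites)]
  within <- stats::ave(seq_len(cfg$n_sites), locus, FUN = seq_along)
  sites <- data.frame(chrom = locus, pos = 10L + 30L * (within - 1L),
                      ref = "A", alt = "T", locus_id = locus,
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, sites, ids)
  truth <- structure(list(
    samples = data.frame(sample_id = ids, population = labels, kind = kind,
                         stringsAsFactors = FALSE),
    q_matrix = qmat,
    clone_registry = registry,
    freq = fr$freq, ancestral = fr$ancestral,
    config = cfg), class = "sim_truth")
  list(gm = gm, truth = truth)
}

#' Expand a clone registry into all true clone pairs
#'
#' The registry lists (source, clone) edges; clones of one source form a
#' single lineage, so the true clonal relation is the transitive closure.
#'
#' @param truth a `sim_truth` from [simulate_genotypes()].
#' @return data.frame of all unordered true clone pairs (`a`, `b`), or an
#'   empty data.frame when the registry is empty.
#' @export
true_clone_pairs <- function(truth) {
  reg <- truth$clone_registry
  if (is.null(reg) || nrow(reg) == 0) {
    return(data.frame(a = character(0), b = character(0)))
  }
  comp <- connected_components(unique(c(reg$source, reg$clone)),
                               reg[, c("source", "clone")])
  pairs <- do.call(rbind, lapply(comp, function(members) {
    if (length(members) < 2) return(NULL)
    idx <- t(utils::combn(sort(members), 2))
    data.frame(a = idx[, 1], b = idx[, 2], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  pairs
}

#' Write simulation truth as structured text
#'
#' @param truth a `sim_truth`.
#' @param path output file path (tab-delimited sections).
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# sim_truth seed=%d", truth$config$seed), con)
  writeLines("## samples", con)
  utils::write.table(truth$samples, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("## clone_registry", con)
  if (!is.null(truth$clone_registry)) {
    utils::write.table(truth$clone_registry, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(truth$q_matrix)) {
    writeLines("## q_matrix", con)
    utils::write.table(data.frame(sample_id = rownames(truth$q_matrix),
                                  truth$q_matrix, check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
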