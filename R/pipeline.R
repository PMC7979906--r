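#' Pipeline run configuration
#'
#' Exactly one input source is active: a VCF + sample-metadata pair, or a
#' simulation config (in which case the simulated inputs are written next to
#' the results so the run is self-documenting).
#'
#' @param vcf,metadata paths to the input VCF and sample-metadata table
#'   (both or neither).
#' @param sim a [sim_config()] (alternative to `vcf`).
#' @param filter a [filter_config()].
#' @param clonality_threshold conserved-heterozygosity threshold.
#' @param block_size jackknife block size in SNPs (default 500).
#' @param dendrogram_k optional number of groups to cut the UPGMA tree into
#'   (default: number of populations).
#' @param n_axes PCA axes to report.
#' @param f3_tests optional list of `c(target, source1, source2)` label
#'   triples; `f4_tests` likewise quadruples. Skipped when NULL.
#' @param f4_tests see `f3_tests`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded (with the config hash) in every output.
#' @return a `run_config` list.
#' @export
run_config <- function(vcf = NULL, metadata = NULL, sim = NULL,
                       filter = filter_config(), clonality_threshold = 0.485,
                       block_size = 500L, dendrogram_k = NULL, n_axes = 6L,
                       f3_tests = NULL, f4_tests = NULL,
                       out_dir = "radclone_run", seed = 1L) {
  if (is.null(sim) == is.null(vcf)) {
    abort("exactly one of `vcf` or `sim` must be given")
  }
  if (!is.null(vcf) && is.null(metadata)) abort("metadata table required with a VCF input")
  structure(list(vcf = vcf, metadata = metadata, sim = sim, filter = filter,
                 clonality_threshold = clonality_threshold,
                 block_size = as.integer(block_size),
                 dendrogram_k = dendrogram_k, n_axes = as.integer(n_axes),
                 f3_tests = f3_tests, f4_tests = f4_tests,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, mirroring the order of a post-genotyping population study:
#' load or simulate genotypes, site filtering, IBS distances + UPGMA
#' dendrogram + genotype PCA, pairwise clonality screen, and population
#' statistics (Ho/He/Fis, pairwise Fst, optional f3/f4). Every table is
#' written tab-delimited under `cfg$out_dir` with a `#` header carrying the
#' seed and a config hash; a `MANIFEST.txt` lists the outputs. Rerunning
#' with the same config reproduces identical files. A stage failure aborts
#' with a stage-named error after writing a `FAILED` marker.
#'
#' @param cfg a [run_config()].
#' @return list of class `run_report`: filter report, dendrogram groups,
#'   clonal partition, population summary, Fst matrix, f-statistics, paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("radclone seed=%d config=%s", cfg$seed, object_hash(cfg))
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write_stamped_table(df, p, stamp)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(stamp, paste("FAILED at stage:", name), conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      abort("stage %s failed: %s", name, conditionMessage(e))
    })
  }

  # --- input stage -----------------------------------------------------
  truth <- NULL
  loaded <- stage("input", {
    if (!is.null(cfg$sim)) {
      simulated <- simulate_genotypes(cfg$sim)
      truth <- simulated$truth
      write_vcf(simulated$gm, file.path(cfg$out_dir, "simulated.vcf"))
      paths[["simulated.vcf"]] <- file.path(cfg$out_dir, "simulated.vcf")
      emit(data.frame(sample_id = truth$samples$sample_id,
                      population = truth$samples$population,
                      kind = truth$samples$kind), "sample_metadata.tsv")
      write_sim_truth(truth, file.path(cfg$out_dir, "sim_truth.txt"))
      paths[["sim_truth.txt"]] <- file.path(cfg$out_dir, "sim_truth.txt")
      list(gm = simulated$gm,
           pm = population_map(truth$samples$sample_id, truth$samples$population),
           truth = truth)
    } else {
      md <- read_sample_metadata(cfg$metadata)
      list(gm = read_vcf(cfg$vcf),
           pm = population_map(md$sample_id, md$population), truth = NULL)
    }
  })
  gm <- loaded$gm
  pm <- loaded$pm

  # --- filter stage ----------------------------------------------------
  filtered <- stage("filter", apply_filters(gm, cfg$filter))
  gm <- filtered$gm
  emit(as.data.frame(filtered$report), "filter_report.tsv")

  # --- structure stage -------------------------------------------------
  pops <- unique(pm[gm$samples])
  k <- cfg$dendrogram_k %||% length(pops)
  str_res <- stage("structure", {
    dm <- ibs_distance(gm)
    hc <- upgma_cluster(dm)
    groups <- cut_dendrogram(hc, k = min(k, n_samples(gm)))
    pca <- genotype_pca(gm, n_axes = min(cfg$n_axes, n_samples(gm)))
    export_newick(hc, file.path(cfg$out_dir, "dendrogram.nwk"))
    paths[["dendrogram.nwk"]] <- file.path(cfg$out_dir, "dendrogram.nwk")
    emit(data.frame(sample_id = rownames(dm), round(dm, 6), check.names = FALSE),
         "ibs_distance.tsv")
    emit(data.frame(sample_id = rownames(pca$scores), group = groups,
                    round(pca$scores, 6), check.names = FALSE), "pca_scores.tsv")
    emit(data.frame(axis = paste0("PC", seq_along(pca$eigenvalues)),
                    eigenvalue = pca$eigenvalues,
                    contribution_ratio = pca$contribution_ratios),
         "pca_contributions.tsv")
    list(dm = dm, hc = hc, groups = groups, pca = pca)
  })

  # --- clonality stage -------------------------------------------------
  clones <- stage("clonality",
                  clonal_clusters(gm, threshold = cfg$clonality_threshold))
  emit(clones$table, "het_conservation_pairs.tsv")
  emit(clones$membership, "clonal_groups.tsv")

  # --- popgen stage ----------------------------------------------------
  pg <- stage("popgen", {
    summary <- heterozygosity_fis(gm, pm)
    fst <- pairwise_fst(gm, pm)
    fstats <- list()
    for (tr in cfg$f3_tests %||% list()) {
      fstats[[length(fstats) + 1L]] <-
        f3(gm, tr[1], tr[2], tr[3], pm = pm, block_size = cfg$block_size)
    }
    for (qd in cfg$f4_tests %||% list()) {
      fstats[[length(fstats) + 1L]] <-
        f4(gm, qd[1], qd[2], qd[3], qd[4], pm = pm, block_size = cfg$block_size)
    }
    list(summary = summary, fst = fst, fstats = fstats)
  })
  emit(pg$summary, "pop_summary.tsv")
  emit(data.frame(population = rownames(pg$fst$fst), pg$fst$fst,
                  check.names = FALSE), "fst_matrix.tsv")
  if (length(pg$fstats)) {
    emit(do.call(rbind, lapply(pg$fstats, as.data.frame)), "f_statistics.tsv")
  }

  writeLines(c(paste("#", stamp), sort(names(paths))),
             file.path(cfg$out_dir, "MANIFEST.txt"))
  structure(list(config = cfg, stamp = stamp,
                 filter_report = filtered$report,
                 groups = str_res$groups, pca = str_res$pca,
                 clonal = clones, pop_summary = pg$summary,
                 fst = pg$fst, fstats = pg$fstats,
                 truth = loaded$truth, gm = gm, paths = paths),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("radclone run:", x$stamp, "\n")
  print(x$filter_report)
  cat(sprintf("dendrogram cut: %d groups; PCA axes retained: %d\n",
              length(unique(x$groups)), ncol(x$pca$scores)))
  print(x$clonal)
  print(x$fst)
  if (length(x$fstats)) for (f in x$fstats) print(f)
  invisible(x)
}
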