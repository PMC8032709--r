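#' Pipeline configuration
#'
#' One configuration object driving [run_pipeline()]. The global `seed` fans
#' out to every stochastic stage through stage-specific offsets, so enabling
#' or disabling one stage does not perturb another's random stream.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "filter", "classify", "panel", "genotype", "network",
#'   "njtree", "popgen")` in dependency order.
#' @param n_clones,n_sites simulation size.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param filter a [filter_config()].
#' @param panel a [panel_config()].
#' @param n_samples_per_lineage,n_markers,missing_rate chip cohort shape.
#' @param n_bootstrap NJ bootstrap replicates.
#' @param n_perm AMOVA permutations.
#' @param epsilon median-joining relaxation.
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "filter", "classify",
                                       "panel", "genotype", "network",
                                       "njtree", "popgen"),
                            n_clones = 4, n_sites = 10000,
                            sim = sim_config(), filter = filter_config(),
                            panel = panel_config(),
                            n_samples_per_lineage = 107, n_markers = 41,
                            missing_rate = 0.01,
                            n_bootstrap = 200, n_perm = 900, epsilon = 0,
                            out_dir = tempfile("clonediv_run_"),
                            seed = 1L) {
  known <- c("simulate", "filter", "classify", "panel", "genotype",
             "network", "njtree", "popgen")
  if (!all(stages %in% known)) {
    stop_clonediv("unknown stage name", "invalid_argument")
  }
  sim$seed <- seed
  structure(list(stages = known[known %in% stages], n_clones = n_clones,
                 n_sites = n_sites, sim = sim, filter = filter,
                 panel = panel,
                 n_samples_per_lineage = n_samples_per_lineage,
                 n_markers = n_markers, missing_rate = missing_rate,
                 n_bootstrap = n_bootstrap, n_perm = n_perm,
                 epsilon = epsilon, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

need_stage <- function(state, what, stage, needed_by) {
  if (is.null(state[[what]])) {
    stop_clonediv(sprintf(
      "stage '%s' requires output of stage '%s' which did not run",
      needed_by, stage), "dependency_error")
  }
  state[[what]]
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order: simulate (genealogy,
#' planted mutations, read evidence, three callers, chip cohort) -> filter
#' (three-caller consensus + site filters) -> classify (SNP / SC-SNV /
#' Sh-SNV) -> panel (chip marker selection) -> genotype (multilocus genotype
#' collapsing) -> network (median-joining) -> njtree (bootstrapped NJ tree of
#' genotypes, reference outgroup) -> popgen (PCoA + AMOVA Phi-PT on lineage
#' truth groups). Writes standard-format artifacts (VCF, TSV, FASTA, Newick,
#' NEXUS) under `out_dir` and returns a manifest of parameters, per-stage
#' counts and output checksums; the same config and seed reproduce identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @return List of class `run_manifest`: `parameters`, `counts`, `files`
#'   (md5 checksums), plus in-memory `results` for downstream use.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  counts <- list()
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  if ("simulate" %in% config$stages) {
    gen <- simulate_genealogy(config$n_clones, config$sim)
    truth <- plant_mutations(gen, config$sim, config$n_sites)
    obs <- if (nrow(truth) > 0) simulate_read_counts(truth, config$sim)
    callsets <- simulate_callers(truth, config$sim)
    cohort <- simulate_chip_cohort(
      gen, config$n_samples_per_lineage, config$n_markers,
      config$missing_rate, seed = config$seed + 10L
    )
    state$genealogy <- gen; state$truth <- truth; state$obs <- obs
    state$callsets <- callsets; state$cohort <- cohort
    counts$simulate <- list(n_truth_sites = nrow(truth),
                            n_cohort_samples = nrow(cohort$genotypes))
    p <- file.path(config$out_dir, "cohort_genotypes.tsv")
    write_genotype_table(cohort$genotypes, p); emit(p)
    for (nm in names(callsets)) {
      p <- file.path(config$out_dir, sprintf("calls_%s.vcf", nm))
      write_call_vcf(callsets[[nm]], p); emit(p)
    }
  }

  if ("filter" %in% config$stages) {
    callsets <- need_stage(state, "callsets", "simulate", "filter")
    obs <- need_stage(state, "obs", "simulate", "filter")
    filt <- consensus_filter(callsets, obs, config$filter)
    state$filtered <- filt
    reason_tags <- unlist(strsplit(filt$sites$reasons[!filt$sites$pass], ","))
    counts$filter <- list(
      n_consensus = nrow(filt$sites),
      n_pass = sum(filt$sites$pass),
      reasons = as.list(table(reason_tags))
    )
    p <- file.path(config$out_dir, "filtered.vcf")
    write_call_vcf(filt$retained, p); emit(p)
    p <- file.path(config$out_dir, "filter_audit.tsv")
    write.table(filt$audit[, setdiff(names(filt$audit),
                                     c("alt_offsets", "ref_offsets"))],
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }

  if ("classify" %in% config$stages) {
    filt <- need_stage(state, "filtered", "filter", "classify")
    cls <- partition_variants(filt$retained$calls)
    state$classified <- cls
    counts$classify <- as.list(cls$summary$class_counts)
    counts$classify$tstv <- cls$summary$tstv
    p <- file.path(config$out_dir, "classified.tsv")
    write.table(cls$variants, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p)
  }

  if ("panel" %in% config$stages) {
    cls <- need_stage(state, "classified", "classify", "panel")
    panel <- select_panel(cls$variants, config$panel,
                          seed = config$seed + 20L)
    state$panel <- panel
    counts$panel <- list(n_markers = nrow(panel),
                         n_sc = sum(panel$class == "SC_het"),
                         n_sh = sum(panel$class == "Sh_het"))
    p <- file.path(config$out_dir, "panel.tsv")
    write.table(panel, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }

  if ("genotype" %in% config$stages) {
    cohort <- need_stage(state, "cohort", "simulate", "genotype")
    mlg <- collapse_genotypes(cohort$genotypes)
    state$mlg <- mlg
    counts$genotype <- list(
      n_genotypes = length(mlg$genotypes),
      n_singletons = sum(vapply(mlg$genotypes, function(g) g$singleton,
                                logical(1)))
    )
    p <- file.path(config$out_dir, "genotype_membership.tsv")
    write.table(mlg_membership(mlg), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p)
  }

  if ("network" %in% config$stages) {
    mlg <- need_stage(state, "mlg", "genotype", "network")
    prof <- mlg_profiles(mlg)
    prof[is.na(prof)] <- 0L          # complete profiles for the network
    net <- median_joining(prof, epsilon = config$epsilon)
    state$network <- net
    counts$network <- list(n_nodes = nrow(net$nodes),
                           n_medians = sum(net$is_median),
                           n_edges = nrow(net$edges))
    p <- file.path(config$out_dir, "network_edges.tsv")
    write_network(net, p, file.path(config$out_dir, "network.nex"))
    emit(p); emit(file.path(config$out_dir, "network.nex"))
  }

  if ("njtree" %in% config$stages) {
    mlg <- need_stage(state, "mlg", "genotype", "njtree")
    prof <- mlg_profiles(mlg)
    seqs <- code_genotypes(prof, outgroup = "REF")
    phy <- bootstrap_supports(seqs, n_reps = config$n_bootstrap,
                              seed = config$seed + 30L)
    phy <- root_with_outgroup(phy, "REF")
    state$tree <- phy
    counts$njtree <- list(n_tips = length(phy$tip.label),
                          n_bootstrap = config$n_bootstrap)
    p <- file.path(config$out_dir, "genotypes_nj.nwk")
    write_newick(phy, p); emit(p)
    p <- file.path(config$out_dir, "genotypes.fasta")
    write_coded_fasta(seqs, p); emit(p)
  }

  if ("popgen" %in% config$stages) {
    cohort <- need_stage(state, "cohort", "simulate", "popgen")
    mlg <- need_stage(state, "mlg", "genotype", "popgen")
    prof <- mlg_profiles(mlg)
    prof[is.na(prof)] <- 0L
    d2g <- codominant_distance_matrix(prof)
    pc <- pcoa(d2g)
    # AMOVA at sample level on lineage truth groups
    gm <- cohort$genotypes
    gm[is.na(gm)] <- 0L
    d2s <- codominant_distance_matrix(gm)
    am <- amova_phipt(d2s, cohort$groups, n_perm = config$n_perm,
                      seed = config$seed + 40L)
    state$pcoa <- pc; state$amova <- am
    counts$popgen <- list(pco1_pct = pc$percent[1],
                          phi_pt = am$phi_pt, p_value = am$p_value)
    p <- file.path(config$out_dir, "pcoa_coordinates.tsv")
    hdr <- paste0("# percent variance: ",
                  paste(sprintf("%.2f", pc$percent), collapse = ", "))
    writeLines(hdr, p)
    suppressWarnings(write.table(
      data.frame(taxon = rownames(pc$coordinates), pc$coordinates),
      p, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    emit(p)
    p <- file.path(config$out_dir, "amova.tsv")
    write.table(data.frame(
      SS_among = am$SS_among, SS_within = am$SS_within,
      SS_total = am$SS_total, df_among = am$df_among,
      df_within = am$df_within, Va = am$Va, Vw = am$Vw,
      phi_pt = am$phi_pt, p_value = am$p_value, n_perm = am$n_perm
    ), p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }

  structure(list(
    parameters = config,
    counts = counts,
    files = tools::md5sum(files),
    results = state
  ), class = "run_manifest")
}
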