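#' Configuration for the end-to-end pipeline
#'
#' @param seed master seed; every stage derives its seeds from it
#' @param spec a [synthetic_spec()]
#' @param lambda residue-base scale (used when `calibrate = FALSE`)
#' @param calibrate re-calibrate lambda to `target_affinity`
#' @param target_affinity kcal/mol, default 8
#' @param k_tether tether spring constant (default: packaged value)
#' @param umbrella list: `centers`, `k_bias`, `n_steps`, `stride`
#' @param n_equil_steps equilibrium-run length for the PCA stage
#' @param n_cluster_frames frames for the clustering stage
#' @param k_clusters clusters for the Q-clustering stage
#' @param out_dir output directory (created); default `tempdir()` subdir
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, spec = synthetic_spec(),
                            lambda = NULL, calibrate = FALSE,
                            target_affinity = 8, k_tether = NULL,
                            umbrella = list(), n_equil_steps = 4e4,
                            n_cluster_frames = 30, k_clusters = 3,
                            out_dir = NULL) {
  dc <- demo_config()
  if (is.null(lambda)) lambda <- dc$lambda
  if (is.null(k_tether)) k_tether <- dc$k_tether
  um <- utils::modifyList(list(centers = seq(4, 30, length.out = 10),
                               k_bias = dc$umbrella$k_bias,
                               n_steps = 3e4,
                               stride = dc$umbrella$stride), umbrella)
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), sprintf("rbdsumo_pipeline_%d", seed))
  structure(list(seed = as.integer(seed), spec = spec, lambda = lambda,
                 calibrate = calibrate, target_affinity = target_affinity,
                 k_tether = k_tether, umbrella = um,
                 n_equil_steps = n_equil_steps,
                 n_cluster_frames = n_cluster_frames,
                 k_clusters = k_clusters, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  key <- config[setdiff(names(config), "out_dir")]
  paste(unname(tools::md5sum(
    local({
      f <- tempfile()
      saveRDS(key, f, version = 2)
      f
    }))), collapse = "")
}

#' Run the full analysis pipeline on the synthetic system
#'
#' Executes, in order: fixture generation, an equilibrium receptor
#' simulation, PCA (PC0), Q-matrix clustering and the inter-domain contact
#' map, SUMO-mimic bias construction with Q_c and frustration screening,
#' residue-base potential construction (optionally re-calibrated to the
#' target affinity), umbrella series for the plain and the tethered
#' receptor-ligand system, WHAM in 1D and 2D, binding free energies and
#' their difference, steered-dissociation pathway classification, and the
#' equilibrium-shift ratio. A JSON report with every stage's numbers and
#' artifact paths is written to the output directory. Re-running with an
#' unchanged configuration reloads the cached report (keyed by a
#' configuration hash).
#'
#' @param config a [pipeline_config()]
#' @param force ignore the cache and recompute
#' @return the report (named list), invisibly also written as JSON
#' @export
run_full_pipeline <- function(config = pipeline_config(), force = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  report_path <- file.path(config$out_dir, "report.json")
  if (!force && file.exists(report_path)) {
    old <- jsonlite::read_json(report_path, simplifyVector = TRUE)
    if (identical(old$config_hash, hash)) return(invisible(old))
  }
  report <- list(config_hash = hash, seed = config$seed, stages = list())
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      report$failed_stage <- name
      jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial report at ", report_path, ")", call. = FALSE)
    })
    res
  }

  ## 1: fixtures
  sys <- stage("generate", function() demo_system(config$lambda, config$spec))
  pdb_path <- file.path(config$out_dir, "reference_complex.pdb")
  write_pdb_cg(sys$complex, pdb_path)
  report$stages$generate <- list(
    n_sites = nrow(sys$complex$sites),
    n_planted_contacts = nrow(sys$counts),
    reference_pdb = pdb_path)

  ## 2: equilibrium simulation of the free receptor (the hinge motion
  ## only shows in the ligand-free ensemble; the receptor chain occupies
  ## the leading rows of the complex, so the fitted model projects
  ## complex frames too)
  ridx <- chain_sites(sys$complex, "A")
  topo_free <- build_topology(sys$receptor$closed)
  equil <- stage("equilibrium", function()
    run_langevin(topo_free, temperature = 300,
                 n_steps = config$n_equil_steps, stride = 100,
                 seed = config$seed))
  ens <- cg_ensemble(sys$receptor$closed, equil$frames)

  ## 3: PCA / PC0
  pca <- stage("pca", function()
    fit_pca(ens, open_reference = sys$receptor$open))
  pc0_open <- project_pc0(pca, coords(sys$receptor$open))
  pc0_closed <- project_pc0(pca, coords(sys$receptor$closed))
  report$stages$pca <- list(
    variance_fraction_pc0 = pca$explained_variance[1] /
      max(sum(pca$explained_variance), 1e-300),
    pc0_open_reference = pc0_open, pc0_closed_reference = pc0_closed)

  ## 4: clustering + contact map on a predicted-ensemble stand-in
  cl_ens <- stage("ensemble", function()
    make_bimodal_ensemble(config$spec, n_frames = config$n_cluster_frames))
  qm <- pairwise_q_matrix(cl_ens, q_spec(pair_scope = "inter_domain"))
  cl <- cluster_by_q(qm, k = config$k_clusters)
  cmap <- contact_frequency_map(cl_ens, "dom1", "dom2")
  qmat_path <- file.path(config$out_dir, "qmatrix.tsv")
  utils::write.table(qm, qmat_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  report$stages$clustering <- list(
    k = config$k_clusters, sizes = as.vector(table(cl$labels)),
    representatives = cl$representatives, qmatrix_tsv = qmat_path,
    n_consensus_contacts = nrow(cmap))

  ## 5: SUMO-mimic screening: sheet-bias construction, Q_c screen and
  ## frustration count on the peptide-partner complex
  simcx <- make_sim_partner_complex()
  biases <- stage("sumo_biases", function()
    make_sumo_biases(simcx, "SIM", "beta2"))
  displaced <- set_coords(simcx, {
    xy <- coords(simcx)
    pidx <- annotation_sites(simcx, "SIM")
    xy[pidx, 3] <- xy[pidx, 3] + 20
    xy
  })
  qc_native <- q_to_template(simcx, simcx)
  qc_displaced <- q_to_template(displaced, simcx)
  fz <- frustration_zscores(simcx, contact_potential(), n_decoys = 500,
                            seed = config$seed)
  report$stages$screening <- list(
    n_sheet_restraints = nrow(biases$sheet$pairs),
    qc_native = qc_native, qc_displaced = qc_displaced,
    selected = screen_by_qc(c(qc_native, qc_displaced)),
    n_minimally_frustrated = attr(fz, "n_minimally_frustrated"))

  ## 6: potential scale
  um <- config$umbrella
  lambda <- config$lambda
  if (config$calibrate) {
    cal <- stage("calibrate", function()
      calibrate_scale(function(l) demo_system(l, config$spec)$topology,
                      target = config$target_affinity, seed = config$seed,
                      window_centers = um$centers, k_bias = um$k_bias,
                      n_steps_per_window = um$n_steps, stride = um$stride))
    lambda <- cal$lambda
    sys <- demo_system(lambda, config$spec)
  }
  report$stages$potential <- list(lambda = lambda,
                                  n_wells = nrow(sys$topology$rb))

  ## 7: umbrella + WHAM for the plain and the tethered system
  tether <- bias_tether_between(sys$complex, "dom1", "dom2",
                                k = config$k_tether,
                                n_pairs = demo_config()$tether_pairs)
  est_plain <- stage("umbrella_untethered", function()
    estimate_affinity(sys$topology, window_centers = um$centers,
                      k_bias = um$k_bias, n_steps_per_window = um$n_steps,
                      stride = um$stride, seed = config$seed + 11L,
                      pca_model = pca))
  est_teth <- stage("umbrella_tethered", function()
    estimate_affinity(sys$topology, base_biases = list(tether),
                      window_centers = um$centers, k_bias = um$k_bias,
                      n_steps_per_window = um$n_steps, stride = um$stride,
                      seed = config$seed + 23L, pca_model = pca))
  s2d <- wham_2d(est_plain$dataset, axis_pair = c("r", "pc0"))
  dd <- delta_delta_g(est_teth$affinity, est_plain$affinity)
  surf_path <- file.path(config$out_dir, "fes_1d.tsv")
  utils::write.table(
    data.frame(r = est_plain$surface$mids, F = est_plain$surface$F,
               se = est_plain$surface$se),
    surf_path, sep = "\t", row.names = FALSE)
  report$stages$free_energy <- list(
    dg_untethered = est_plain$affinity$dg, se_untethered = est_plain$affinity$se,
    dg_tethered = est_teth$affinity$dg, se_tethered = est_teth$affinity$se,
    ddg = dd$ddg, ddg_se = dd$se, surface_tsv = surf_path,
    fes2d_dims = dim(s2d$F))

  ## 8: steered dissociation + pathway classification (the clamp here is
  ## stiff: the pathway comparison mirrors the fully bound partner, while
  ## the ddG tether above is the calibrated, softer restraint)
  paths <- stage("pathways", function() {
    classify_demo_dissociation(sys, pca, pc0_open, pc0_closed,
                               seed = config$seed, n_runs = 3)
  })
  report$stages$pathways <- paths

  ## 9: thermodynamics
  report$stages$thermodynamics <- list(
    ddg = dd$ddg, shift_ratio = shift_ratio(dd$ddg))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  report$report_path <- report_path
  invisible(report)
}

#' Steered dissociation runs and pathway classification on the demo system
#'
#' Pulls the ligand from the bound pose to the unbound range with a moving
#' harmonic restraint, with and without the cross-link tether, and
#' classifies each trajectory as path I (receptor opens before the ligand
#' unbinds) or path II (receptor stays closed throughout unbinding).
#'
#' @param sys a [demo_system()]
#' @param pca fitted [fit_pca()] model over the receptor sites
#' @param pc0_open,pc0_closed projections of the two reference conformers
#' @param k_tether tether spring constant for the tethered runs
#' @param seed integer
#' @param n_runs trajectories per condition
#' @param n_steps steps per steered run
#' @return list with the per-run classifications and majority calls
#' @export
classify_demo_dissociation <- function(sys, pca, pc0_open, pc0_closed,
                                       k_tether = 5, seed = 1, n_runs = 5,
                                       n_steps = 1e5) {
  topo_struct <- cg_structure(sys$topology$sites, sys$topology$annotations)
  pidx <- annotation_sites(topo_struct, "pocket")
  lidx <- chain_sites(topo_struct, "B")
  r0 <- compute_r(sys$complex)
  thresholds <- list(
    r_bound = r0 + 4, r_unbound = 22,
    pc0_open_min = pc0_closed + 0.6 * (pc0_open - pc0_closed),
    pc0_closed_max = pc0_closed + 0.45 * (pc0_open - pc0_closed))
  tether <- bias_tether_between(sys$complex, "dom1", "dom2", k = k_tether)
  run_one <- function(tethered, s) {
    pull <- bias_harmonic_r(pidx, lidx, k = 2, center = r0,
                            center_end = 30)
    bb <- if (tethered) list(tether, pull) else list(pull)
    res <- run_langevin(sys$topology, biases = bb, temperature = 300,
                        n_steps = n_steps, stride = 100, seed = s)
    op <- frame_order_params(res$frames, topo_struct, pca_model = pca)
    classify_pathway(op, thresholds)
  }
  runs <- data.frame(
    tethered = rep(c(FALSE, TRUE), each = n_runs),
    run = rep(seq_len(n_runs), 2))
  runs$pathway <- vapply(seq_len(nrow(runs)), function(r)
    run_one(runs$tethered[r],
            (seed + 7L * r + 1000L * runs$tethered[r]) %% 2147483647L),
    character(1))
  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  list(runs = runs,
       untethered_majority = majority(runs$pathway[!runs$tethered]),
       tethered_majority = majority(runs$pathway[runs$tethered]),
       thresholds = thresholds)
}
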