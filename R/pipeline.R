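#' Run the full trajectory-analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order on a trajectory that is
#' either read from disk or generated by a synthetic spec, writing
#' machine-readable outputs (CSV/GraphML/JSON) to the output directory and
#' returning a run report. Identical config + seed reproduces byte-identical
#' outputs.
#'
#' Config fields (R list, or path to a YAML file):
#' \itemize{
#'   \item \code{input}: \code{list(topology=, trajectory=, stride=)} — or
#'   \item \code{synthetic}: \code{list(kind=, ...)} with kinds
#'     \code{"gaussian"} (n_res, sigma, n_frames, blocks),
#'     \code{"two_state"} (n_res, p_a, n_frames, jitter, scale),
#'     \code{"hbond_toy"} (f, n_frames, mode),
#'     \code{"fold"} (fold, n_res, sigma, n_frames);
#'   \item \code{stages}: subset of rmsd, rmsf, rg, sasa, dccm, pca, fel,
#'     hbonds, rin, sse, consensus (default: all applicable);
#'   \item \code{seed}: integer seed for every stochastic generator;
#'   \item \code{output_dir}: where outputs are written;
#'   \item optional per-stage settings: \code{selections} (rmsd/rmsf/dccm/pca
#'     expressions), \code{fel} (n_bins, temperature), \code{hbond}
#'     (dist_cutoff, angle_cutoff), \code{rin} (threshold, max_frames),
#'     \code{sasa} (probe_radius, n_points), \code{consensus} (scores = CSV
#'     path).
#' }
#'
#' @param config configuration list or YAML file path.
#' @return object of class \code{"RunReport"}: list with \code{files}
#'   (per-stage output paths), \code{summary} (scalar summaries),
#'   \code{results} (in-memory result objects), \code{config},
#'   \code{provenance}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$output_dir)) stop("config needs an output_dir")
  if (!is.null(cfg$input) && !is.null(cfg$synthetic)) {
    stop("config must name exactly one of input/synthetic")
  }
  if (is.null(cfg$input) && is.null(cfg$synthetic)) {
    stop("config must name exactly one of input/synthetic")
  }
  if (!is.null(cfg$input)) {
    if (!file.exists(cfg$input$trajectory %||% "")) {
      stop("trajectory file not found: ", cfg$input$trajectory)
    }
    if (!is.null(cfg$input$topology) && !file.exists(cfg$input$topology)) {
      stop("topology file not found: ", cfg$input$topology)
    }
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)

  traj <- .pipeline_trajectory(cfg, seed)
  has_backbone <- all(c("N", "CA", "C", "O") %in% traj$topology$atoms$name)
  default_stages <- c("rmsd", "rmsf", "rg", "dccm", "pca", "fel",
                      if (has_backbone) c("sasa", "hbonds", "rin", "sse"))
  stages <- cfg$stages %||% default_stages

  files <- list(); summary <- list(); results <- list()
  outfile <- function(name) file.path(cfg$output_dir, name)
  log_stage <- function(name, ...) {
    message(sprintf("[trajscope] stage %-9s %s", name, paste0(...)))
  }
  sel <- function(stage, default) cfg$selections[[stage]] %||% default

  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return()
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  rmsd_res <- NULL; rg_res <- NULL; pca_res <- NULL
  run_stage("rmsd", function() {
    r <- rmsd_series(traj, selection = sel("rmsd", "name N CA C"))
    rmsd_res <<- r
    files$rmsd <<- outfile("rmsd.csv"); write_result_csv(r, files$rmsd)
    summary$rmsd_mean_A <<- mean(r$values)
    summary$rmsd_final_A <<- r$values[length(r$values)]
    log_stage("rmsd", sprintf("mean %.3f A over %d frames",
                              mean(r$values), length(r$values)))
  })
  run_stage("rmsf", function() {
    r <- rmsf_profile(traj, selection = sel("rmsf", "calpha"))
    results$rmsf <<- r
    files$rmsf <<- outfile("rmsf.csv"); write_result_csv(r, files$rmsf)
    summary$rmsf_mean_A <<- mean(r$values)
    log_stage("rmsf", sprintf("mean %.3f A over %d residues",
                              mean(r$values), length(r$values)))
  })
  run_stage("rg", function() {
    r <- rg_series(traj)
    rg_res <<- r
    files$rg <<- outfile("rg.csv"); write_result_csv(r, files$rg)
    summary$rg_mean_A <<- mean(r$values)
    log_stage("rg", sprintf("mean %.3f A", mean(r$values)))
  })
  run_stage("sasa", function() {
    ps <- cfg$sasa %||% list()
    r <- sasa_series(traj, probe_radius = ps$probe_radius %||% 1.4,
                     n_points = ps$n_points %||% 960L)
    files$sasa <<- outfile("sasa.csv"); write_result_csv(r, files$sasa)
    per_res <- sasa(traj$topology, get_frame(traj, 1),
                    probe_radius = ps$probe_radius %||% 1.4,
                    n_points = ps$n_points %||% 960L)$per_residue
    results$sasa_per_residue <<- per_res
    files$sasa_per_residue <<- outfile("sasa_per_residue.csv")
    write_result_csv(per_res, files$sasa_per_residue)
    summary$sasa_mean_A2 <<- mean(r$values)
    log_stage("sasa", sprintf("mean total %.1f A^2", mean(r$values)))
  })
  run_stage("dccm", function() {
    r <- dccm(traj, selection = sel("dccm", "calpha"))
    results$dccm <<- r
    files$dccm <<- outfile("dccm.csv"); write_dccm_csv(r, files$dccm)
    log_stage("dccm", sprintf("%dx%d matrix", nrow(r$matrix), ncol(r$matrix)))
  })
  run_stage("pca", function() {
    r <- pca_covariance(traj, selection = sel("pca", "calpha"))
    pca_res <<- r
    results$pca <<- r
    results$pc1_loading <<- mode_profile(r, 1L)$profile
    spec <- data.frame(mode = seq_along(r$eigenvalues),
                       eigenvalue_A2 = r$eigenvalues,
                       variance_fraction = r$variance_fractions)
    files$pca <<- outfile("pca_spectrum.csv")
    utils::write.csv(spec, files$pca, row.names = FALSE)
    proj <- project_onto_pcs(traj, r, k = min(2L, length(r$eigenvalues)))
    files$pca_projections <<- outfile("pca_projections.csv")
    utils::write.csv(as.data.frame(proj), files$pca_projections,
                     row.names = FALSE)
    summary$pca_trace_A2 <<- r$trace
    summary$pca_first3_variance_pct <<-
      100 * sum(r$variance_fractions[seq_len(min(3, length(r$variance_fractions)))])
    log_stage("pca", sprintf("trace %.3f A^2, first-3 %.1f%%",
                             r$trace, summary$pca_first3_variance_pct))
  })
  run_stage("fel", function() {
    if (is.null(rg_res)) rg_res <<- rg_series(traj)
    if (is.null(rmsd_res)) rmsd_res <<- rmsd_series(traj)
    fp <- cfg$fel %||% list()
    grid <- compute_fel(rg_res, rmsd_res,
                        n_bins = unlist(fp$n_bins %||% c(50L, 50L)),
                        temperature = fp$temperature %||% 300)
    basins <- locate_minima(grid)
    results$fel <<- grid
    files$fel <<- outfile("fel.csv"); write_fel_csv(grid, files$fel)
    bs <- lapply(basins, function(b) list(
      minimum_bin = as.integer(b$minimum_bin), G_min = b$G_min,
      depth = b$depth, population_fraction = b$population_fraction))
    files$fel_basins <<- outfile("fel_basins.json")
    jsonlite::write_json(bs, files$fel_basins, auto_unbox = TRUE, digits = NA)
    rep_frame <- representative_frame(grid, basins[[1]], rg_res, rmsd_res)
    files$representative <<- outfile("representative.pdb")
    write_structure(traj$topology, files$representative,
                    frame = get_frame(traj, rep_frame))
    summary$basin_count <<- length(basins)
    summary$representative_frame <<- rep_frame
    log_stage("fel", sprintf("%d basin(s); representative frame %d",
                             length(basins), rep_frame))
  })
  run_stage("hbonds", function() {
    hp <- cfg$hbond %||% list()
    tab <- hbond_occupancy(traj,
                           dist_cutoff = hp$dist_cutoff %||% 3.0,
                           angle_cutoff = hp$angle_cutoff %||% 20)
    results$hbonds <<- tab
    files$hbonds <<- outfile("hbond_occupancy.csv")
    utils::write.csv(as.data.frame(tab), files$hbonds, row.names = FALSE)
    summary$hbond_pairs <<- nrow(tab)
    log_stage("hbonds", sprintf("%d donor-acceptor pairs", nrow(tab)))
  })
  run_stage("rin", function() {
    rp <- cfg$rin %||% list()
    hp <- cfg$hbond %||% list()
    rin <- build_rin(traj,
                     occupancy_threshold = rp$threshold %||% 10,
                     max_frames = rp$max_frames %||% 1000L,
                     dist_cutoff = hp$dist_cutoff %||% 3.0,
                     angle_cutoff = hp$angle_cutoff %||% 20)
    results$rin <<- rin
    files$rin_graphml <<- outfile("rin.graphml")
    files$rin_edges <<- outfile("rin_edges.csv")
    write_rin(rin, files$rin_graphml, files$rin_edges)
    summary$rin_edge_count <<- nrow(rin$edges)
    log_stage("rin", sprintf("%d edges at >=%g%% occupancy",
                             nrow(rin$edges), rp$threshold %||% 10))
  })
  run_stage("sse", function() {
    r <- sse_statistics(traj)
    results$sse <<- r
    files$sse <<- outfile("sse_timeline.csv")
    files$sse_summary <<- outfile("sse_summary.json")
    write_sse(r, files$sse, files$sse_summary)
    summary$helix_pct_total <<- r$helix_pct_total
    summary$strand_pct_total <<- r$strand_pct_total
    summary$total_sse_pct <<- r$total_sse_pct
    log_stage("sse", sprintf("helix %.1f%%, strand %.1f%%",
                             r$helix_pct_total, r$strand_pct_total))
  })
  run_stage("consensus", function() {
    cp <- cfg$consensus
    if (is.null(cp$scores)) stop("consensus stage needs a scores CSV path")
    res <- consensus_rank(read_score_table(cp$scores))
    results$consensus <<- res
    files$consensus <<- outfile("consensus.csv")
    write_consensus_csv(res, files$consensus)
    summary$top_variant <<- res$variant[1]
    log_stage("consensus", sprintf("top variant %s (%d tools)",
                                   res$variant[1], res$deleterious_count[1]))
  })

  provenance <- list(
    package_version = as.character(utils::packageVersion("trajscope")),
    seed = seed,
    config_hash = .config_hash(cfg),
    n_frames = n_frames(traj), n_atoms = n_atoms(traj$topology)
  )
  report <- structure(list(files = files, summary = summary,
                           results = results, config = cfg,
                           provenance = provenance),
                      class = "RunReport")
  jsonlite::write_json(list(files = lapply(files, identity),
                            summary = summary, provenance = provenance),
                       file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.pipeline_trajectory <- function(cfg, seed) {
  if (!is.null(cfg$input)) {
    topo <- if (!is.null(cfg$input$topology)) read_pdb(cfg$input$topology)
    return(read_trajectory(cfg$input$trajectory, topo,
                           stride = cfg$input$stride %||% 1L))
  }
  sp <- cfg$synthetic
  switch(sp$kind,
    gaussian = {
      ref <- make_ca_chain(sp$n_res %||% 20L)
      blocks <- lapply(sp$blocks %||% list(), function(b) {
        list(a = unlist(b$a), b = unlist(b$b), rho = b$rho)
      })
      make_gaussian_ensemble(ref, sigma = sp$sigma %||% 0.5,
                             n_frames = sp$n_frames %||% 1000L,
                             seed = seed, blocks = blocks)
    },
    two_state = {
      ref <- make_ca_chain(sp$n_res %||% 20L)
      make_two_state_trajectory(ref, ref$xyz, ref$xyz * (sp$scale %||% 1.15),
                                p_a = sp$p_a %||% 0.7,
                                n_frames = sp$n_frames %||% 1000L,
                                jitter = sp$jitter %||% 0.1, seed = seed,
                                assignment = sp$assignment %||% "schedule")
    },
    hbond_toy = make_hbond_toy(sp$f %||% 0.25, sp$n_frames %||% 100L,
                               mode = sp$mode %||% "schedule", seed = seed),
    fold = {
      ref <- make_toy_protein(sp$n_res %||% 15L, fold = sp$fold %||% "helix")
      make_gaussian_ensemble(ref, sigma = sp$sigma %||% 0.1,
                             n_frames = sp$n_frames %||% 50L, seed = seed)
    },
    stop("unknown synthetic kind '", sp$kind, "'")
  )
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport:", length(x$files), "output file(s) in",
      x$config$output_dir, "\n")
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.numeric(v)) format(v, digits = 6) else v))
  }
  invisible(x)
}

#' Compare two pipeline runs (e.g. wild-type vs variant)
#'
#' Aligns scalar summaries and per-residue profiles (RMSF, per-residue SASA,
#' PC1 loadings) of two run reports and tabulates A, B and the difference —
#' the variant-versus-wild-type framing of comparative MD studies.
#'
#' @param report_a,report_b \code{\link{run_pipeline}} reports.
#' @return list with \code{scalars} (data.frame metric/a/b/delta) and
#'   \code{profiles} (named list of data.frames author_resid/a/b/delta).
#' @export
compare_runs <- function(report_a, report_b) {
  shared <- intersect(names(report_a$summary), names(report_b$summary))
  shared <- shared[vapply(shared, function(nm) {
    is.numeric(report_a$summary[[nm]]) && is.numeric(report_b$summary[[nm]])
  }, logical(1))]
  prof_names <- intersect(
    intersect(names(report_a$results), names(report_b$results)),
    c("rmsf", "sasa_per_residue", "pc1_loading"))
  if (length(shared) == 0L && length(prof_names) == 0L) {
    stop("reports share no comparable metrics")
  }
  scalars <- data.frame(
    metric = shared,
    a = vapply(shared, function(nm) report_a$summary[[nm]], numeric(1)),
    b = vapply(shared, function(nm) report_b$summary[[nm]], numeric(1)))
  scalars$delta <- scalars$b - scalars$a
  rownames(scalars) <- NULL
  profiles <- lapply(prof_names, function(nm) {
    pa <- report_a$results[[nm]]; pb <- report_b$results[[nm]]
    if (length(pa$values) != length(pb$values)) {
      stop("profile '", nm, "' has different residue counts in the two runs")
    }
    data.frame(author_resid = pa$author_resid, a = pa$values, b = pb$values,
               delta = pb$values - pa$values)
  })
  names(profiles) <- prof_names
  list(scalars = scalars, profiles = profiles)
}
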