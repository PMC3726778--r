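#' Configuration for a full three-model comparison run
#'
#' Defaults follow the canonical analysis scale (pool 10,000, ensemble 50);
#' desk-scale runs (tests, demos) pass smaller values.
#'
#' @param pool_size Random-pool size per flexible model.
#' @param ensemble_size Selected sub-ensemble size M.
#' @param ga A [ga_config()].
#' @param generator A [generator_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @export
compare_config <- function(pool_size = 10000L, ensemble_size = 50L,
                           ga = ga_config(), generator = generator_config(),
                           seed = 1L) {
  structure(list(pool_size = as.integer(pool_size),
                 ensemble_size = as.integer(ensemble_size),
                 ga = ga, generator = generator, seed = as.integer(seed)),
            class = "compare_config")
}

#' The three model topologies of a scenario's chain
#'
#' Given a two-arm scenario, builds the three competing architectures:
#' \describe{
#'   \item{hinged}{rigid arms separated by a flexible hinge, flexible tail.}
#'   \item{linear}{arms fused collinearly through a rigid helical spacer of
#'     the hinge's residue count (1.5 Angstrom rise per residue), flexible
#'     tail.}
#'   \item{extended}{a single fully rigid body: the linear rod with the tail
#'     continued as a rigid helical rod.}
#' }
#'
#' @param spec A [scenario_spec()]; its hinge length sizes the spacer.
#' @return List with `hinged` and `linear` (`segment_topology`) and
#'   `extended` (a `bead_model`).
#' @export
three_model_topologies <- function(spec) {
  arms <- scenario_arms(spec)
  a1 <- spec$arm1_residues; h <- spec$hinge_residues
  a2 <- spec$arm2_residues; ct <- spec$ct_residues
  hinged_spec <- spec
  hinged_spec$name <- "L_shape"   # any flexible-tail preset; only geometry used
  hinged <- if (h > 0L) {
    segs <- list(segment("rigid", 1L, a1, "arm1", arms$arm1),
                 segment("flexible", a1 + 1L, a1 + h, "hinge"),
                 segment("rigid", a1 + h + 1L, a1 + h + a2, "arm2", arms$arm2))
    if (ct > 0L)
      segs <- c(segs, list(segment("flexible", a1 + h + a2 + 1L,
                                   a1 + h + a2 + ct, "CT")))
    build_topology(segs, "hinged")
  } else NULL
  spacer_n <- h
  linear_body <- if (h > 0L) fuse_collinear(list(
    arms$arm1, helical_spacer(spacer_n, derive_seed(spec$seed, 4L)),
    arms$arm2)) else fuse_collinear(arms)
  n_lin <- a1 + spacer_n + a2
  lin_segs <- list(segment("rigid", 1L, n_lin, "arm1+spacer+arm2",
                           linear_body))
  if (ct > 0L)
    lin_segs <- c(lin_segs, list(segment("flexible", n_lin + 1L,
                                         n_lin + ct, "CT")))
  linear <- build_topology(lin_segs, "linear")
  extended <- fuse_collinear(list(
    linear_body,
    helical_spacer(max(ct, 2L), derive_seed(spec$seed, 3L))))
  list(hinged = hinged, linear = linear, extended = extended)
}

run_eom_stage <- function(topology, data_curve, run_config, stage_seed) {
  pool <- generate_pool(topology, run_config$pool_size,
                        run_config$generator, seed = stage_seed)
  pool <- precompute_curves(pool, data_curve$q)
  ga <- run_config$ga
  ga$seed <- derive_seed(stage_seed, 1L, salt = 23L)
  ens <- ga_select(pool, data_curve, M = run_config$ensemble_size,
                   config = ga)
  summary <- summarize_distributions(pool, ens)
  shapes <- tryCatch(classify_shapes(pool, ens), error = function(e) NULL)
  list(pool = pool, ensemble = ens, summary = summary, shapes = shapes)
}

#' Run the full three-model flexibility comparison
#'
#' Fits the one data curve three ways: (1) the fully rigid linear-extended
#' body by a single rigid fit; (2) the linear model (rigid rod, flexible
#' tail) and (3) the hinged model (flexible hinge and tail) by random-pool
#' generation plus genetic-algorithm sub-ensemble selection. Collects
#' chi-square values, residuals, pool-versus-selected distributions, shape
#' fractions, data-side Guinier Rg and the Kratky transform, and ranks the
#' models by chi-square. Stage failures are caught and reported; the partial
#' report is preserved.
#'
#' @param data_curve Data `scattering_curve` with `sigma` (checked up front).
#' @param spec A [scenario_spec()] describing the chain architecture.
#' @param run_config A [compare_config()].
#' @return An object of class `comparison_report`.
#' @export
run_three_model_comparison <- function(data_curve, spec,
                                       run_config = compare_config()) {
  if (is.null(data_curve$sigma))
    stop("data curve has no sigma column; uncertainties are required")
  models <- three_model_topologies(spec)
  report <- list(fits = list(), summaries = list(), shapes = list(),
                 errors = list(),
                 provenance = list(seed = run_config$seed,
                                   pool_size = run_config$pool_size,
                                   ensemble_size = run_config$ensemble_size,
                                   scenario = spec$name,
                                   package_version =
                                     as.character(utils::packageVersion("saxsens"))))
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  report$guinier <- try_stage("guinier", guinier_rg(data_curve))
  report$kratky <- try_stage("kratky", kratky_transform(data_curve))
  ext_fit <- try_stage("linear_extended",
                       fit_rigid_model(models$extended, data_curve,
                                       model_label = "linear extended"))
  if (!is.null(ext_fit)) report$fits$linear_extended <- ext_fit
  lin <- try_stage("linear_SR_rod", run_eom_stage(
    models$linear, data_curve, run_config,
    derive_seed(run_config$seed, 2L, salt = 31L)))
  if (!is.null(lin)) {
    report$fits$linear <- lin$ensemble$fit
    report$summaries$linear <- lin$summary
  }
  if (!is.null(models$hinged)) {
    hin <- try_stage("hinged", run_eom_stage(
      models$hinged, data_curve, run_config,
      derive_seed(run_config$seed, 3L, salt = 31L)))
    if (!is.null(hin)) {
      report$fits$hinged <- hin$ensemble$fit
      report$summaries$hinged <- hin$summary
      report$shapes$hinged_pool <- classify_shapes(hin$pool)
      if (!is.null(hin$shapes)) report$shapes$hinged_selected <- hin$shapes
    }
  }
  chis <- vapply(report$fits, `[[`, 0, "chi2")
  report$ranking <- names(sort(chis))
  report$chi2 <- chis
  structure(report, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$provenance$scenario, "\n")
  if (!is.null(x$guinier))
    cat(sprintf("  data Guinier Rg: %.1f A\n", x$guinier$rg))
  for (nm in names(x$chi2))
    cat(sprintf("  chi2 %-16s %.3f\n", nm, x$chi2[[nm]]))
  if (length(x$ranking))
    cat("  ranking (best first):", paste(x$ranking, collapse = " < "), "\n")
  if (!is.null(x$summaries$hinged)) print(x$summaries$hinged)
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write a comparison report to a directory
#'
#' JSON summary plus per-model residual tables and histogram TSVs.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    scenario = report$provenance$scenario,
    chi2 = as.list(report$chi2),
    ranking = report$ranking,
    guinier_rg = if (!is.null(report$guinier)) report$guinier$rg else NULL,
    rg_rms = lapply(report$summaries, function(s)
      list(pool = s$rg_rms_pool, selected = s$rg_rms_selected,
           peaks = s$peak_count_selected)),
    shapes = report$shapes,
    provenance = report$provenance,
    errors = report$errors)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    utils::write.table(
      data.frame(q = f$q, residual = f$residuals),
      file.path(dir, paste0("residuals_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(report$summaries)) {
    s <- report$summaries[[nm]]
    h <- s$rg_hist
    utils::write.table(
      data.frame(rg_lo = h$breaks[-length(h$breaks)], rg_hi = h$breaks[-1L],
                 pool = h$pool, selected = h$selected),
      file.path(dir, paste0("rg_hist_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
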