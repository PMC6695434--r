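# End-to-end drivers: a shape survey over many structures and the
# diffusion/phase-diagram chain from simulated (or model) crowding curves
# to the reaction-rate optimum.

#' Shape survey over a set of structures
#'
#' For each structure (file path or atom cloud): calliper diameters, the
#' equivalent ellipsoid, (alpha, beta) descriptors, volume, model surface
#' area and isoperimetric quotient. Per-file failures are logged and the
#' survey continues. Output row order follows the input order.
#'
#' @param structures character vector of PDB paths, or a list of
#'   [atom_cloud()]s.
#' @param include_hydrogens passed to [read_structure()].
#' @param bw_alpha,bw_beta smoothing bandwidths for the shape
#'   distribution.
#' @return list: `table` (one row per structure), `distribution` (a
#'   `shape_distribution`), `mode`, `failures` (named character vector).
#' @export
pipeline_shape_survey <- function(structures, include_hydrogens = FALSE,
                                  bw_alpha = 0.05, bw_beta = 0.05) {
  nm <- if (is.character(structures)) basename(structures)
        else sprintf("cloud_%03d", seq_along(structures))
  rows <- list()
  failures <- character()
  for (k in seq_along(structures)) {
    res <- tryCatch({
      cl <- if (is.character(structures))
        read_structure(structures[[k]], include_hydrogens)
      else structures[[k]]
      cal <- calliper(cl)
      ell <- steric_ellipsoid(cl)
      s <- shape_ab(ell)
      V <- ellipsoid_volume(ell)
      A <- surface_area_model(s$alpha, ifelse(is.na(s$beta), 0, s$beta), V)
      data.frame(id = nm[k],
                 caliper_max = cal$max, caliper_min = cal$min,
                 caliper_ratio = cal$ratio,
                 a = ell$a, b = ell$b, c = ell$c,
                 alpha = s$alpha, beta = s$beta, class = s$class,
                 V = V, A = A,
                 quotient = 36 * pi * V^2 / A^3,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[nm[k]] <- res
      message(sprintf("shape survey: skipping %s (%s)", nm[k], res))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) stop("no structure could be processed")
  tab <- do.call(rbind, rows)
  dist <- shape_distribution(tab[!is.na(tab$alpha), ],
                             bw_alpha = bw_alpha, bw_beta = bw_beta)
  list(table = tab, distribution = dist, mode = dist$mode,
       failures = failures)
}

#' Diffusion phase diagram and reaction-rate optimum
#'
#' Chains the simulator and the crowding model: for each aspect ratio,
#' extracts phi_c from a ladder of volume fractions (or, in the
#' `"quadratic"` shortcut mode, skips simulation entirely), then scans
#' phi * D(phi)/D0 and reports the optimum.
#'
#' @param alpha_values aspect ratios to study.
#' @param phi_values simulation volume fractions (>= 4).
#' @param config base [sim_config()].
#' @param model `"tokuyama"` (simulate, fit, optimize) or `"quadratic"`
#'   (no simulation; requires `phi_c_fixed`).
#' @param phi_c_fixed critical volume fraction for the shortcut mode.
#' @param seed ladder seed.
#' @return list: `phi_c` (per-alpha table, simulated mode), `optimum`
#'   (per-alpha argmax of phi * D), `tables` (per-alpha D(phi)).
#' @export
pipeline_diffusion_phase_diagram <- function(alpha_values = c(1.0, 1.6),
                                             phi_values = c(0.15, 0.25,
                                                            0.35, 0.45),
                                             config = sim_config(),
                                             model = c("tokuyama",
                                                       "quadratic"),
                                             phi_c_fixed = 0.58,
                                             seed = config$seed) {
  model <- match.arg(model)
  if (model == "quadratic") {
    opt <- rate_optimum("quadratic", phi_c = phi_c_fixed)
    return(list(phi_c = data.frame(alpha = NA, phi_c = phi_c_fixed),
                optimum = data.frame(alpha = NA,
                                     phi_opt = opt$phi_opt,
                                     phi_percent = opt$phi_percent,
                                     value = opt$value),
                tables = list()))
  }
  fits <- lapply(alpha_values, function(a)
    phi_c_pipeline(a, phi_values, config, seed = seed))
  phi_c_tab <- data.frame(
    alpha = alpha_values,
    phi_c = vapply(fits, function(f) f$fit$phi_c, 0),
    kappa = vapply(fits, function(f) f$fit$kappa, 0))
  opt <- do.call(rbind, lapply(seq_along(alpha_values), function(k) {
    ro <- rate_optimum("tokuyama", phi_c = phi_c_tab$phi_c[k],
                       kappa = phi_c_tab$kappa[k])
    data.frame(alpha = alpha_values[k], phi_opt = ro$phi_opt,
               phi_percent = ro$phi_percent, value = ro$value)
  }))
  names(fits) <- sprintf("alpha_%s", alpha_values)
  list(phi_c = phi_c_tab, optimum = opt,
       tables = lapply(fits, `[[`, "table"))
}
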