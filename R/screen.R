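#' Normalize plate luminescence to DMSO viability
#'
#' Viability of a well is its luminescence divided by the mean DMSO
#' luminescence on the same plate and model; replicate compound wells at a
#' concentration are averaged after normalization. Concentrations tagged
#' `"nM"` in a `unit` column are converted to the canonical unit, uM.
#'
#' @param plate data.frame with columns `plate_id`, `well`, `compound_id`
#'   (`"DMSO"` for control wells), `concentration`, `model_id`,
#'   `luminescence`; optional `unit` (`"uM"` default, `"nM"` accepted).
#' @return data.frame with one row per (compound_id, model_id,
#'   concentration): `viability`, sorted ascending in concentration within
#'   each curve.
#' @export
normalize_viability <- function(plate) {
  need <- c("plate_id", "well", "compound_id", "concentration", "model_id",
            "luminescence")
  if (!all(need %in% names(plate)))
    stop("plate data needs columns ", paste(need, collapse = ", "))
  dt <- data.table::as.data.table(plate)
  if ("unit" %in% names(dt)) {
    dt[, concentration := ifelse(unit == "nM", concentration / 1000,
                                 concentration)]
    dt[, unit := NULL]
  }
  if (any(dt$luminescence < 0)) stop("luminescence must be >= 0")
  if (any(dt$compound_id != "DMSO" & !(dt$concentration > 0)))
    stop("compound concentrations must be > 0")
  dmso <- dt[compound_id == "DMSO",
             .(dmso_mean = mean(luminescence)), by = .(plate_id, model_id)]
  missing <- unique(dt[compound_id != "DMSO", .(plate_id, model_id)])[
    !dmso, on = c("plate_id", "model_id")]
  if (nrow(missing))
    stop("no DMSO wells for plate/model: ",
         paste(missing$plate_id, missing$model_id, sep = "/", collapse = ", "))
  if (any(dmso$dmso_mean <= 0))
    stop("zero mean DMSO signal on plate(s): ",
         paste(unique(dmso[dmso_mean <= 0]$plate_id), collapse = ", "))
  dt <- dmso[dt[compound_id != "DMSO"], on = c("plate_id", "model_id")]
  dt[, viability := luminescence / dmso_mean]
  out <- dt[, .(viability = mean(viability)),
            by = .(compound_id, model_id, concentration)]
  out <- out[order(compound_id, model_id, concentration)]
  as.data.frame(out)
}

#' Range-normalized AUC over log10 concentration
#'
#' Trapezoidal integral of viability over log10(concentration), divided by
#' the log10 dose range, so a constant viability `v` scores exactly `v` and
#' curves with different dose ranges are comparable. Viability is used as-is
#' (no clipping).
#'
#' @param concentration dose vector (uM), >= 2 distinct positive values.
#' @param viability matching viability fractions.
#' @return scalar AUC in `[0, Inf)`.
#' @export
compute_auc <- function(concentration, viability) {
  ok <- concentration > 0
  concentration <- concentration[ok]; viability <- viability[ok]
  o <- order(concentration)
  x <- log10(concentration[o]); y <- viability[o]
  if (length(unique(x)) < 2L)
    stop("AUC needs at least 2 distinct nonzero concentrations")
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc / (max(x) - min(x))
}

#' Cross-model AUC Z-scores for one compound
#'
#' `z_m = (auc_m - mean(auc)) / sd(auc)` with the sample (n-1) standard
#' deviation; negative Z marks model-specific sensitivity. Zero variance
#' yields all-zero Z with a degenerate flag.
#'
#' @param aucs named numeric vector, one AUC per model (>= 2 models).
#' @return list with `z` (named vector) and `degenerate` flag.
#' @export
auc_zscores <- function(aucs) {
  if (length(aucs) < 2L) stop("need AUCs for at least 2 models")
  s <- stats::sd(aucs)
  if (s == 0 || !is.finite(s))
    return(list(z = stats::setNames(rep(0, length(aucs)), names(aucs)),
                degenerate = TRUE))
  list(z = (aucs - mean(aucs)) / s, degenerate = FALSE)
}

# 4PL: v(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)
fourpl <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `v(c) = bottom + (top - bottom)/(1 + (c/ic50)^hill)`
#' over the nonzero doses; zero-dose points only anchor the `top`
#' initialization. Initialization: `top = max(v)`, `bottom = min(v)`,
#' `ic50 = geometric mean of doses`, `hill = 1`. Bounds: `ic50 > 0` (fit in
#' log space), `hill` in (0.1, 10], `bottom >= 0`. Optimization is L-BFGS-B
#' followed by a Nelder-Mead polish; a fit on an effectively flat curve or a
#' failed optimization is flagged non-convergent with `ic50 = NA`, never a
#' silent number.
#'
#' @param concentration dose vector (uM); >= 4 distinct nonzero doses.
#' @param viability matching viability fractions.
#' @return list of class `dose_response_fit`: `top`, `bottom`, `ic50`,
#'   `hill`, `rss`, `converged`.
#' @export
fit_dose_response <- function(concentration, viability) {
  stopifnot(length(concentration) == length(viability))
  zero <- concentration == 0
  c0 <- concentration[!zero]; v0 <- viability[!zero]
  if (length(unique(c0)) < 4L)
    stop("4PL fit needs at least 4 distinct nonzero concentrations")
  top0 <- max(viability)  # zero-dose points anchor the top
  bot0 <- min(v0)
  # flat curve: no dose effect to fit an IC50 to
  if (diff(range(v0)) < 1e-9) {
    return(structure(list(top = top0, bottom = bot0, ic50 = NA_real_,
                          hill = NA_real_, rss = 0, converged = FALSE),
                     class = "dose_response_fit"))
  }
  obj <- function(p) {
    r <- v0 - fourpl(c0, p[1], p[2], exp(p[3]), p[4])
    sum(r * r)
  }
  start <- c(top0, bot0, mean(log(c0)), 1)
  lower <- c(-Inf, 0, log(min(c0)) - log(1e4), 0.1 + 1e-9)
  upper <- c(Inf, Inf, log(max(c0)) + log(1e4), 10)
  fit <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 1e3)),
    error = function(e) NULL)
  # Nelder-Mead polish (log-barrier-free: clamp inside obj via penalty)
  pol_obj <- function(p) {
    if (p[2] < 0 || p[4] <= 0.1 || p[4] > 10) return(Inf)
    obj(p)
  }
  if (!is.null(fit)) {
    pol <- stats::optim(fit$par, pol_obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (pol$value <= fit$value) fit <- pol
  } else {
    fit <- stats::optim(start, pol_obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
  }
  p <- fit$par
  ic50 <- exp(p[3])
  # non-convergence / boundary degeneracies: IC50 pushed out of the dose
  # window by orders of magnitude means the data do not determine it
  converged <- is.finite(fit$value) &&
    ic50 > min(c0) / 1e3 && ic50 < max(c0) * 1e3 &&
    (p[1] - p[2]) > 1e-6
  structure(list(top = p[1], bottom = p[2],
                 ic50 = if (converged) ic50 else NA_real_,
                 hill = p[4], rss = fit$value, converged = converged),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("4PL fit: top %.3f, bottom %.3f, IC50 %.4g uM, hill %.2f (rss %.3g)\n",
                x$top, x$bottom, x$ic50, x$hill, x$rss))
  else cat("4PL fit: non-convergent (no defined IC50)\n")
  invisible(x)
}

#' Full screen analysis: normalize, AUC, Z-scores, 4PL fits
#'
#' @param plate raw plate data (see [normalize_viability()]).
#' @param focus_model model of interest for hit ranking (default the first
#'   model id alphabetically).
#' @param fit_curves fit a 4PL per (compound, focus model) (default TRUE).
#' @return object of class `screen_result`: `curves` (normalized viability
#'   data.frame), `auc` (compound x model matrix), `z` (compound x model
#'   matrix, rows centred), `degenerate` (logical per compound), `fits`
#'   (named list of [fit_dose_response()] results for the focus model),
#'   `focus_model`.
#' @export
analyze_screen <- function(plate, focus_model = NULL, fit_curves = TRUE) {
  curves <- normalize_viability(plate)
  compounds <- sort(unique(curves$compound_id))
  models <- sort(unique(curves$model_id))
  if (is.null(focus_model)) focus_model <- models[1]
  if (!focus_model %in% models)
    stop("focus_model '", focus_model, "' not present; models: ",
         paste(models, collapse = ", "))
  auc <- matrix(NA_real_, length(compounds), length(models),
                dimnames = list(compounds, models))
  for (i in seq_len(nrow(auc))) for (m in models) {
    sub <- curves[curves$compound_id == compounds[i] & curves$model_id == m, ]
    if (nrow(sub) >= 2L)
      auc[i, m] <- compute_auc(sub$concentration, sub$viability)
  }
  z <- auc; degenerate <- stats::setNames(logical(length(compounds)), compounds)
  for (i in seq_len(nrow(auc))) {
    zz <- auc_zscores(auc[i, ])
    z[i, ] <- zz$z
    degenerate[i] <- zz$degenerate
  }
  fits <- list()
  if (fit_curves) {
    for (cmp in compounds) {
      sub <- curves[curves$compound_id == cmp & curves$model_id == focus_model, ]
      fits[[cmp]] <- tryCatch(
        fit_dose_response(sub$concentration, sub$viability),
        error = function(e) structure(
          list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
               hill = NA_real_, rss = NA_real_, converged = FALSE),
          class = "dose_response_fit"))
    }
  }
  structure(list(curves = curves, auc = auc, z = z, degenerate = degenerate,
                 fits = fits, focus_model = focus_model),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d compounds x %d models (focus: %s)\n",
              nrow(x$auc), ncol(x$auc), x$focus_model))
  invisible(x)
}

#' Select screen hits by sensitivity Z-score and plasma concentration
#'
#' A compound is a hit when its focus-model Z-score is at most `z_max`
#' (model-specific sensitivity) AND its fitted IC50 lies at or below
#' `plasma_factor` times the clinically achieved plasma concentration
#' ("below or around" the plasma level). Compounds without a plasma value are
#' evaluated on the Z criterion alone and flagged.
#'
#' @param result a [analyze_screen()] result.
#' @param plasma named numeric vector: compound id -> plasma concentration
#'   (uM, same unit as curve concentrations).
#' @param z_max Z-score ceiling (default -0.5).
#' @param plasma_factor multiple of the plasma level the IC50 may reach
#'   (default 2).
#' @return data.frame per compound: `z_focus`, `ic50`, `plasma_uM`,
#'   `z_pass`, `plasma_pass` (NA when no plasma value), `plasma_known`,
#'   `hit`; sorted by `z_focus`.
#' @export
select_hits <- function(result, plasma = numeric(), z_max = -0.5,
                        plasma_factor = 2.0) {
  stopifnot(inherits(result, "screen_result"))
  compounds <- rownames(result$z)
  z_focus <- result$z[, result$focus_model]
  ic50 <- vapply(compounds, function(cmp) {
    f <- result$fits[[cmp]]
    if (is.null(f)) NA_real_ else f$ic50
  }, 0)
  pl <- plasma[compounds]
  names(pl) <- compounds
  z_pass <- z_focus <= z_max
  plasma_known <- !is.na(pl)
  plasma_pass <- ifelse(plasma_known, !is.na(ic50) & ic50 <= plasma_factor * pl,
                        NA)
  hit <- z_pass & (is.na(plasma_pass) | plasma_pass)
  out <- data.frame(compound_id = compounds, z_focus = z_focus, ic50 = ic50,
                    plasma_uM = as.numeric(pl), z_pass = z_pass,
                    plasma_pass = plasma_pass, plasma_known = plasma_known,
                    hit = hit, row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$z_focus), ]
}
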