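#' Measure one arbor variant end to end
#'
#' Runs the full per-arbor measurement chain: surface mesh, effective fractal
#' dimension D (exact voxelization + sliding box count + scaling-window fit),
#' surface area A_s, convex-hull bounding metrics A_b and V_b, branch volume
#' V_m, and the orientation-averaged profile P over a dilated spine layer.
#'
#' @param x an [arbor].
#' @param boxcount_resolution voxels/um for box counting (4 in the full
#'   protocol; 2 is a practical reduced setting for large ensembles).
#' @param profile_resolution voxels/um for the profile grid (1).
#' @param viewpoints number of Fibonacci viewpoints (201).
#' @param spine_radius spine-layer dilation radius, um (2).
#' @param spine_density spine-density pre-factor in (0, 1] (default 1).
#' @param volume_resolution voxels/um for V_m (4).
#' @param fit_args list of arguments for [fit_dimension].
#' @return One-row data.frame with D, r_squared, P, A_s, A_b, V_b, V_m and the
#'   derived ratios `P_As`, `As_Ab`, `P_Ab`, `Vm_Vb`.
#' @export
measure_arbor <- function(x, boxcount_resolution = 4, profile_resolution = 1,
                          viewpoints = 201L, spine_radius = 2,
                          spine_density = 1, volume_resolution = 4,
                          fit_args = list()) {
  mesh <- mesh_from_centerline(x)
  A_s <- surface_area(mesh)
  hull <- hull_metrics(mesh$vertices)
  V_m <- model_volume(mesh, volume_resolution)
  gbox <- voxelize(mesh, boxcount_resolution)
  fit <- do.call(fit_dimension, c(list(box_count(gbox)), fit_args))
  gpro <- voxelize(mesh, profile_resolution)
  if (spine_radius > 0) gpro <- dilate_grid(gpro, spine_radius)
  pr <- mean_profile(gpro, fibonacci_directions(viewpoints), A_s = A_s,
                     A_b = hull$A_b, density = spine_density)
  data.frame(D = fit$D, r_squared = fit$r_squared, P = pr$mean_P, A_s = A_s,
             A_b = hull$A_b, V_b = hull$V_b, V_m = as.numeric(V_m),
             P_As = pr$mean_P / A_s, As_Ab = A_s / hull$A_b,
             P_Ab = pr$mean_P / hull$A_b, Vm_Vb = as.numeric(V_m) / hull$V_b)
}

#' Binned averages of a metric against D
#'
#' @param records data.frame with a `D` column (one row per arbor variant).
#' @param metric column name to average.
#' @param n_bins number of equal-width D bins (default 15).
#' @return data.frame `center`, `mean`, `n`; empty bins carry `NA` means and
#'   are flagged, never interpolated.
#' @export
binned_average <- function(records, metric, n_bins = 15L) {
  stopifnot(metric %in% names(records), "D" %in% names(records))
  rng <- range(records$D)
  if (diff(rng) < 1e-12) rng <- rng + c(-0.5, 0.5) * 1e-6
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1L)
  bin <- findInterval(records$D, edges, rightmost.closed = TRUE)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mns <- rep(NA_real_, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  for (b in which(cnt > 0)) mns[b] <- mean(records[[metric]][bin == b])
  data.frame(center = centers, mean = mns, n = cnt, empty = cnt == 0)
}

#' Cubic fit of a metric against D
#'
#' Least-squares third-degree polynomial, the functional form used to
#' summarize how connectivity density and the cost ratios vary with D.
#'
#' @param records data.frame with `D` and the metric column.
#' @param metric column name.
#' @return Numeric coefficients `c(c0, c1, c2, c3)` of
#'   `c0 + c1 D + c2 D^2 + c3 D^3`.
#' @export
fit_cubic <- function(records, metric) {
  stopifnot(metric %in% names(records))
  if (nrow(records) < 5) stop("need at least 5 records for a cubic fit")
  D <- records$D
  if (diff(range(D)) < 1e-9) stop("rank deficiency: all D values equal")
  y <- records[[metric]]
  fit <- lm(y ~ D + I(D^2) + I(D^3))
  cf <- unname(coef(fit))
  if (anyNA(cf)) stop("rank-deficient cubic fit (too few distinct D values)")
  cf
}

cubic_deriv <- function(cf) c(cf[2], 2 * cf[3], 3 * cf[4]) # derivative coefficients

eval_poly <- function(cf, x) {
  out <- 0
  for (k in seq_along(cf)) out <- out + cf[k] * x^(k - 1)
  out
}

#' Derivative-ratio optimization statistics
#'
#' \deqn{R_{PA}(D) = \frac{d(P/A_b)/dD}{d(A_s/A_b)/dD}, \qquad
#'       R_{PV}(D) = \frac{d(P/A_b)/dD}{d(V_m/V_b)/dD}}
#' the rate of change of connectivity density per rate of change of operating
#' cost (R_PA) and of building cost (R_PV), evaluated from the fitted cubics.
#' Grid points where the denominator derivative vanishes are masked `NA`.
#'
#' @param curves an `optimization_curves` object from
#'   [fit_optimization_curves].
#' @param which `"R_PA"` or `"R_PV"`.
#' @param D_grid evaluation grid (defaults to the stored grid).
#' @return Numeric vector of R values on the grid.
#' @export
compute_R <- function(curves, which = c("R_PA", "R_PV"), D_grid = NULL) {
  which <- match.arg(which)
  if (is.null(D_grid)) D_grid <- curves$D_grid
  num <- eval_poly(cubic_deriv(curves$coef$P_Ab), D_grid)
  den_cf <- if (which == "R_PA") curves$coef$As_Ab else curves$coef$Vm_Vb
  den <- eval_poly(cubic_deriv(den_cf), D_grid)
  scale <- max(abs(den), na.rm = TRUE)
  out <- num / den
  out[abs(den) < 1e-10 * max(scale, 1e-300)] <- NA_real_
  if (all(is.na(out))) stop("denominator derivative vanishes on the whole grid")
  out
}

#' Locate the peak of an optimization statistic
#'
#' Grid argmax refined by quadratic interpolation through the three
#' neighboring points. The peak is flagged `interior` when it falls strictly
#' inside the searched range (the data-supported region) rather than in an
#' extrapolated extension.
#'
#' @param R values on `D_grid` (NAs allowed).
#' @param D_grid grid of D values.
#' @param search_range range of D to search (default: whole grid).
#' @return List `D_peak`, `R_peak`, `interior`; for R monotone over the range,
#'   `no_interior_peak = TRUE` and `D_peak = NA`.
#' @export
find_peak <- function(R, D_grid, search_range = range(D_grid)) {
  sel <- which(D_grid >= search_range[1] - 1e-12 &
               D_grid <= search_range[2] + 1e-12 & !is.na(R))
  if (length(sel) < 3) stop("need at least 3 grid points in the search range")
  Rv <- R[sel]
  Dv <- D_grid[sel]
  i <- which.max(Rv)
  if (i == 1L || i == length(Rv)) {
    return(list(D_peak = NA_real_, R_peak = Rv[i], interior = FALSE,
                no_interior_peak = TRUE, boundary = Dv[i]))
  }
  # quadratic refinement through (i-1, i, i+1)
  x <- Dv[(i - 1):(i + 1)]
  y <- Rv[(i - 1):(i + 1)]
  d1 <- (y[3] - y[1]) / (x[3] - x[1])
  d2 <- (y[3] - 2 * y[2] + y[1]) / ((x[2] - x[1]) * (x[3] - x[2]))
  Dp <- if (is.finite(d2) && d2 < 0) x[2] - d1 / d2 else Dv[i]
  if (Dp < x[1] || Dp > x[3]) Dp <- Dv[i]
  list(D_peak = Dp, R_peak = max(Rv), interior = TRUE, no_interior_peak = FALSE)
}

#' Fit the optimization curves of an ensemble
#'
#' Fits third-degree polynomials of P/A_b, A_s/A_b, V_m/V_b (and P/A_s)
#' against D on the raw records, computes the derivative-ratio statistics
#' R_PA and R_PV on a fine D grid over the data range (step 0.001), optionally
#' extended into an extrapolated region flagged separately, and locates the
#' peaks within the data range.
#'
#' @param records data.frame from [measure_arbor] rows.
#' @param grid_step D-grid spacing (default 0.001).
#' @param extrapolate fraction of the data range to extend on each side,
#'   flagged as extrapolated (default 0).
#' @param n_bins bins for the binned averages.
#' @return An `optimization_curves` object.
#' @export
fit_optimization_curves <- function(records, grid_step = 0.001,
                                    extrapolate = 0, n_bins = 15L) {
  metrics <- c("P_As", "As_Ab", "P_Ab", "Vm_Vb")
  cf <- lapply(setNames(metrics, metrics), function(m) fit_cubic(records, m))
  drng <- range(records$D)
  ext <- extrapolate * diff(drng)
  D_grid <- seq(drng[1] - ext, drng[2] + ext, by = grid_step)
  out <- list(coef = cf, D_range = drng, D_grid = D_grid,
              extrapolated = D_grid < drng[1] | D_grid > drng[2],
              binned = lapply(setNames(metrics, metrics), function(m)
                binned_average(records, m, n_bins)),
              n_records = nrow(records))
  class(out) <- "optimization_curves"
  out$R_PA <- compute_R(out, "R_PA")
  out$R_PV <- compute_R(out, "R_PV")
  out$peaks <- list(R_PA = find_peak(out$R_PA, D_grid, drng),
                    R_PV = find_peak(out$R_PV, D_grid, drng))
  out
}

#' @export
print.optimization_curves <- function(x, ...) {
  cat("<optimization_curves> ", x$n_records, " records, D in [",
      format(x$D_range[1], digits = 4), ", ", format(x$D_range[2], digits = 4),
      "]\n", sep = "")
  for (nm in c("R_PA", "R_PV")) {
    p <- x$peaks[[nm]]
    if (isTRUE(p$no_interior_peak)) {
      cat("  ", nm, ": no interior peak (monotone; boundary at D = ",
          format(p$boundary, digits = 4), ")\n", sep = "")
    } else {
      cat("  ", nm, " peak at D = ", format(p$D_peak, digits = 4), "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
plot.optimization_curves <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (m in c("P_As", "As_Ab", "P_Ab", "Vm_Vb")) {
    b <- x$binned[[m]]
    yfit <- eval_poly(x$coef[[m]], x$D_grid)
    plot(x$D_grid, yfit, type = "l", xlab = "D", ylab = m, main = m)
    points(b$center[!b$empty], b$mean[!b$empty], col = "cyan3", pch = 16)
  }
  invisible(x)
}

#' Run the full connectivity-versus-cost pipeline
#'
#' For every input arbor (or generator specification) and every angle-
#' manipulation variant, measures the morphometric record (D, P, A_s, A_b,
#' V_m, V_b and ratios), then fits the optimization curves per group (H-trees
#' and neuron-like arbors are never pooled in one fit) and locates the R_PA
#' and R_PV peaks. Stage failures are caught per arbor and reported in a
#' failure manifest; the pipeline is deterministic given the seed.
#'
#' @param config a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{generators}{list of specs, each a list with `type`
#'     (`"htree"`, `"weaving_htree"`, `"equal_htree"`, `"toy"`) plus the
#'     arguments of the corresponding generator.}
#'   \item{inputs}{character vector of SWC paths (group `"neuron"`).}
#'   \item{alphas, targets}{angle-manipulation grid (optional).}
#'   \item{boxcount}{list(resolution); profile: list(viewpoints, spine_radius,
#'     resolution); volume: list(resolution); fit: arguments for
#'     [fit_dimension].}
#'   \item{seed}{integer; mandatory for stochastic generators.}
#'   \item{output_dir}{if set, writes records.csv, curves.json, peaks.json.}
#' }
#' @param progress emit per-stage messages (default TRUE).
#' @return List with `records`, `curves` (per group), `peaks`, `failures`.
#' @export
run_pipeline <- function(config, progress = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  boxres <- cfg$boxcount$resolution %||% 4
  vres <- cfg$volume$resolution %||% 4
  pres <- cfg$profile$resolution %||% 1
  nview <- cfg$profile$viewpoints %||% 201L
  spine <- cfg$profile$spine_radius %||% 2
  sdens <- cfg$profile$spine_density %||% 1
  fit_args <- cfg$fit %||% list()
  alphas <- cfg$alphas %||% 1
  targets <- cfg$targets %||% "weave"
  say <- function(...) if (progress) message(...)
  arbors <- list()
  for (i in seq_along(cfg$generators)) {
    gs <- cfg$generators[[i]]
    type <- gs$type
    gs$type <- NULL
    if (is.null(gs$seed) && type %in% c("weaving_htree", "toy")) {
      gs$seed <- seed + i
    }
    gen <- switch(type,
                  htree = generate_htree,
                  weaving_htree = generate_weaving_htree,
                  equal_htree = generate_equal_length_htree,
                  toy = generate_toy_arbor,
                  stop("unknown generator type: ", type))
    arbors[[length(arbors) + 1L]] <- list(
      id = paste0(type, "_", i),
      group = if (type == "toy") "neuron" else "htree",
      arbor = do.call(gen, gs))
  }
  for (p in cfg$inputs) {
    arbors[[length(arbors) + 1L]] <- list(id = basename(p), group = "neuron",
                                          arbor = read_swc(p))
  }
  records <- list()
  failures <- list()
  for (a in arbors) {
    variants <- if (identical(alphas, 1) && identical(targets, "weave")) {
      list(list(alpha = 1, target = "none", arbor = a$arbor))
    } else {
      generate_variant_set(a$arbor, alphas, targets)
    }
    for (v in variants) {
      t0 <- proc.time()[3]
      rec <- tryCatch(
        measure_arbor(v$arbor, boxcount_resolution = boxres,
                      profile_resolution = pres, viewpoints = nview,
                      spine_radius = spine, spine_density = sdens,
                      volume_resolution = vres, fit_args = fit_args),
        error = function(e) e)
      if (inherits(rec, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(arbor_id = a$id, alpha = v$alpha, target = v$target,
                     error = conditionMessage(rec))
        say("FAILED ", a$id, " (alpha=", v$alpha, ", ", v$target, "): ",
            conditionMessage(rec))
        next
      }
      rec <- cbind(data.frame(arbor_id = a$id, group = a$group,
                              alpha = v$alpha, target = v$target), rec)
      records[[length(records) + 1L]] <- rec
      say(sprintf("measured %s (alpha=%.2f, %s): D=%.3f [%.1f s]",
                  a$id, v$alpha, v$target, rec$D, proc.time()[3] - t0))
    }
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  curves <- list()
  peaks <- list()
  if (!is.null(records)) {
    for (g in unique(records$group)) {
      sub <- records[records$group == g, ]
      if (nrow(sub) >= 5 && diff(range(sub$D)) > 1e-6) {
        curves[[g]] <- fit_optimization_curves(sub)
        peaks[[g]] <- curves[[g]]$peaks
      } else {
        warning("group '", g, "': too few records (", nrow(sub),
                ") for curve fits; skipping")
      }
    }
  }
  out <- list(records = records, curves = curves, peaks = peaks,
              failures = failures)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(records)) {
      write.csv(records, file.path(cfg$output_dir, "records.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(curves, function(cv) list(coef = cv$coef, D_range = cv$D_range)),
      file.path(cfg$output_dir, "curves.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(peaks, file.path(cfg$output_dir, "peaks.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(failures)) {
      write.csv(failures, file.path(cfg$output_dir, "failures.csv"),
                row.names = FALSE)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
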