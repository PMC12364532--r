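#' Render a paired top/side scene with exact ground truth
#'
#' The synthetic plant is the same cylinder the LEI model assumes: leaf
#' length L at elevation angle theta gives a top silhouette that is a
#' filled ellipse with semi-major axis L cos(theta) (minor axis scaled by
#' the eccentricity) and a side silhouette that is an isoceles triangle —
#' leaves rising from the rosette edge to a central apex L sin(theta)
#' above the soil row, with nothing of the plant below the soil row. The
#' triangle makes height extraction face a non-trivial but analytically
#' known shape; because height uses only the apex, the shape choice cannot
#' bias the LEI.
#'
#' Edges are hard (no anti-aliasing) so pixel-count oracles are exact;
#' optional Gaussian channel noise emulates sensor noise.
#'
#' @param params a \linkS4class{SceneParams}.
#' @param plantId,timestampMin metadata stamped on the returned frames.
#' @return list with elements \code{top} and \code{side}
#'   (\linkS4class{Frame}s), \code{truth} (a \linkS4class{SceneTruth}),
#'   and \code{topMask}, \code{sideMask} (logical ground-truth
#'   silhouettes).
#' @examples
#' sc <- renderScene(SceneParams(leafLengthMm = 20, elevationDeg = 45))
#' leiTrueDeg(sc$truth)  # 45
#' @export
renderScene <- function(params = SceneParams(), plantId = "synthetic",
                        timestampMin = 0) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  L <- params@leafLengthMm
  th <- params@elevationDeg * pi / 180
  e <- params@eccentricity

  rTrue <- L * cos(th) * (1 + e) / 2
  hTrue <- L * sin(th)
  leiTrue <- atan(hTrue / rTrue) * 180 / pi

  # ---- top view: filled rotated ellipse -------------------------------
  H <- params@topDim[1]; W <- params@topDim[2]
  a <- L * cos(th) / params@mmPerPxTop          # semi-major, px
  b <- e * a                                    # semi-minor, px
  cr <- round((H + 1) / 2); cc <- round((W + 1) / 2)
  if (cr - a < 1 || cr + a > H || cc - a < 1 || cc + a > W)
    stop("top-view silhouette (semi-axis ", round(a, 1),
         " px) exceeds the ", H, " x ", W, " frame", call. = FALSE)
  phi <- params@rotationDeg * pi / 180
  x <- matrix(rep(seq_len(W) - cc, each = H), H, W)   # column offset
  y <- matrix(rep(-(seq_len(H) - cr), W), H, W)       # row axis up
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  topMask <- (u / a)^2 + (v / b)^2 <= 1

  # ---- side view: isoceles triangle above the soil row ----------------
  Hs <- params@sideDim[1]; Ws <- params@sideDim[2]
  hPx <- hTrue / params@mmPerPxSide
  halfBase <- L * cos(th) / params@mmPerPxSide
  soil <- params@soilRow
  ccs <- round((Ws + 1) / 2)
  if (soil - hPx < 1 || ccs - halfBase < 1 || ccs + halfBase > Ws)
    stop("side-view silhouette exceeds the ", Hs, " x ", Ws, " frame",
         call. = FALSE)
  sideMask <- matrix(FALSE, Hs, Ws)
  if (hPx > 0 && ceiling(soil - hPx) <= soil - 1L) {
    apex <- soil - hPx                              # continuous row
    for (r in ceiling(apex):(soil - 1L)) {
      f <- (r - apex) / hPx                         # 0 at apex, ~1 at base
      hw <- f * halfBase
      c0 <- ceiling(ccs - hw); c1 <- floor(ccs + hw)
      if (c1 >= c0) sideMask[r, c0:c1] <- TRUE
    }
  }

  paint <- function(mask, dims) {
    px <- array(rep(params@backgroundRgb, each = prod(dims)),
                dim = c(dims, 3L))
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[mask] <- params@plantRgb[ch]
      px[, , ch] <- plane
    }
    if (params@noiseSd > 0) {
      px <- px + stats::rnorm(length(px), 0, params@noiseSd)
      px[px < 0] <- 0; px[px > 1] <- 1
    }
    px
  }
  if (params@noiseSd > 0 && !is.na(params@seed)) set.seed(params@seed)

  top <- Frame(paint(topMask, c(H, W)),
               FrameMeta(plantId, "top", timestampMin))
  side <- Frame(paint(sideMask, c(Hs, Ws)),
                FrameMeta(plantId, "side", timestampMin))
  truth <- new("SceneTruth", rTrueMm = rTrue, hTrueMm = hTrue,
               leiTrueDeg = leiTrue, topPxCount = sum(topMask),
               sidePxCount = sum(sideMask))
  list(top = top, side = side, truth = truth,
       topMask = topMask, sideMask = sideMask)
}

#' Genotype presets for the response simulator
#'
#' Four fixtures emulating the qualitative contrast between wild type and
#' shade-avoidance mutants under high versus low red:far-red light:
#' \describe{
#'   \item{wt_low}{large logistic rise saturating around 10 h, no decay.}
#'   \item{wt_high}{no induced response; circadian-like oscillation only.}
#'   \item{pif4pif5_low}{smaller, slower rise reaching its maximum only
#'     after about 15 h.}
#'   \item{pif7_low}{wild-type-like rise rate but lower maximum, and a
#'     transient response that decays back to baseline after about 20 h.}
#' }
#' The numbers are the package's own fixture choices, picked to reproduce
#' this ordering, not measured values.
#'
#' @param name preset name.
#' @return A \linkS4class{ResponseModel}.
#' @examples
#' responsePreset("pif7_low")
#' @export
responsePreset <- function(name) {
  presets <- list(
    wt_low = ResponseModel(baselineDeg = 22, amplitudeDeg = 25,
                           halftimeMin = 300, riseRatePerMin = 0.015,
                           oscAmpDeg = 1.5, oscPeriodMin = 1440,
                           decayStartMin = NA, plantSdDeg = 2,
                           frameSdDeg = 0.75),
    wt_high = ResponseModel(baselineDeg = 22, amplitudeDeg = 0,
                            halftimeMin = 300, riseRatePerMin = 0.015,
                            oscAmpDeg = 1.5, oscPeriodMin = 1440,
                            decayStartMin = NA, plantSdDeg = 2,
                            frameSdDeg = 0.75),
    pif4pif5_low = ResponseModel(baselineDeg = 22, amplitudeDeg = 12,
                                 halftimeMin = 480,
                                 riseRatePerMin = 0.008,
                                 oscAmpDeg = 1.5, oscPeriodMin = 1440,
                                 decayStartMin = NA, plantSdDeg = 2,
                                 frameSdDeg = 0.75),
    pif7_low = ResponseModel(baselineDeg = 22, amplitudeDeg = 15,
                             halftimeMin = 300, riseRatePerMin = 0.015,
                             oscAmpDeg = 1.5, oscPeriodMin = 1440,
                             decayStartMin = 600, decayTauMin = 240,
                             plantSdDeg = 2, frameSdDeg = 0.75))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

#' Names of the shipped response presets
#' @return character vector.
#' @export
listPresets <- function()
  c("wt_low", "wt_high", "pif4pif5_low", "pif7_low")

#' Simulate per-plant leaf elevation trajectories
#'
#' Draws \code{nPlants} trajectories from a \linkS4class{ResponseModel}
#' over a regular time grid:
#' \code{baseline + b_i + A * plogis(k (t - t50)) * D(t) +
#' osc * sin(2 pi t / period) + eps}, clipped to [0, 89] degrees (see
#' \linkS4class{ResponseModel} for the terms). The same seed always
#' reproduces the same trajectories.
#'
#' @param model a \linkS4class{ResponseModel} or preset name.
#' @param nPlants number of plants.
#' @param durationMin total duration in minutes.
#' @param intervalMin sampling interval in minutes; the grid runs from 0
#'   to \code{durationMin} inclusive and must hold at least two points.
#' @param seed RNG seed; \code{NA} uses the current stream.
#' @return data.frame \code{plant_id, timestamp_min, lei_true_deg}.
#' @examples
#' head(simulateTimecourse("wt_low", 3, 360, 30, seed = 1))
#' @export
simulateTimecourse <- function(model, nPlants, durationMin,
                               intervalMin = 30, seed = NA) {
  if (is.character(model)) model <- responsePreset(model)
  stopifnot(is(model, "ResponseModel"), nPlants >= 1)
  t <- seq(0, durationMin, by = intervalMin)
  if (length(t) < 2L)
    stop("duration and interval must yield at least two timepoints",
         call. = FALSE)
  if (!is.na(seed)) set.seed(seed)
  D <- if (is.na(model@decayStartMin)) rep(1, length(t))
       else exp(-pmax(0, t - model@decayStartMin) / model@decayTauMin)
  fixed <- model@baselineDeg +
    model@amplitudeDeg *
      stats::plogis(model@riseRatePerMin * (t - model@halftimeMin)) * D +
    model@oscAmpDeg * sin(2 * pi * t / model@oscPeriodMin)
  b <- stats::rnorm(nPlants, 0, model@plantSdDeg)
  ids <- sprintf("p%02d", seq_len(nPlants))
  out <- vector("list", nPlants)
  for (i in seq_len(nPlants)) {
    eps <- stats::rnorm(length(t), 0, model@frameSdDeg)
    lei <- pmin(pmax(fixed + b[i] + eps, 0), 89)
    out[[i]] <- data.frame(plant_id = ids[i], timestamp_min = t,
                           lei_true_deg = lei, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# invert the truth formula: the elevation angle theta that makes the
# scene's LEI equal `lei` at eccentricity e (theta = lei when e = 1)
.thetaForLei <- function(leiDeg, e) {
  atan(tan(leiDeg * pi / 180) * (1 + e) / 2) * 180 / pi
}

#' Generate a complete synthetic image dataset
#'
#' Simulates per-plant LEI trajectories, renders a top/side frame pair for
#' every plant and timepoint — choosing each scene's elevation angle so
#' that the scene's true LEI equals the simulated value — and writes the
#' images under the standard filename convention together with a
#' \code{truth.csv} ground-truth table. One seed governs both the
#' trajectory and the image noise; a re-run with the same seed reproduces
#' the dataset exactly.
#'
#' @param model a \linkS4class{ResponseModel} or preset name.
#' @param sceneBase a \linkS4class{SceneParams} supplying geometry, scale
#'   and noise for every frame (its \code{elevationDeg} is overridden per
#'   frame and its \code{seed} is ignored in favour of \code{seed}).
#' @param nPlants,durationMin,intervalMin grid, as in
#'   \code{\link{simulateTimecourse}}.
#' @param seed RNG seed for the whole dataset.
#' @param outDir output directory (created if needed).
#' @return list with \code{dir}, \code{truthCsv}, \code{truth}
#'   (data.frame \code{plant_id, timestamp_min, lei_true_deg, r_true_mm,
#'   h_true_mm}) and \code{nImages}.
#' @export
generateDataset <- function(model, sceneBase = SceneParams(), nPlants,
                            durationMin, intervalMin = 30, seed = 1,
                            outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir, call. = FALSE)
  traj <- simulateTimecourse(model, nPlants, durationMin, intervalMin,
                             seed = seed)
  sceneBase@seed <- NA_real_   # noise rides the seeded stream
  rows <- vector("list", nrow(traj))
  n <- 0L
  for (i in seq_len(nrow(traj))) {
    lei <- traj$lei_true_deg[i]
    sp <- sceneBase
    sp@elevationDeg <- .thetaForLei(lei, sceneBase@eccentricity)
    sc <- renderScene(sp, plantId = traj$plant_id[i],
                      timestampMin = traj$timestamp_min[i])
    for (view in c("top", "side")) {
      fname <- sprintf("%s_%s_%04d.png", traj$plant_id[i], view,
                       as.integer(traj$timestamp_min[i]))
      ok <- tryCatch({
        png::writePNG(sc[[view]]@pixels, file.path(outDir, fname))
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok))
        stop("cannot write ", file.path(outDir, fname), ": ", ok,
             call. = FALSE)
      n <- n + 1L
    }
    rows[[i]] <- data.frame(plant_id = traj$plant_id[i],
                            timestamp_min = traj$timestamp_min[i],
                            lei_true_deg = sc$truth@leiTrueDeg,
                            r_true_mm = sc$truth@rTrueMm,
                            h_true_mm = sc$truth@hTrueMm,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truthCsv <- file.path(outDir, "truth.csv")
  utils::write.csv(truth, truthCsv, row.names = FALSE, quote = FALSE)
  list(dir = outDir, truthCsv = truthCsv, truth = truth, nImages = n)
}
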