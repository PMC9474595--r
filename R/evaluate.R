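#' Cumulative dose-volume histogram
#'
#' Fraction (and absolute cc) of the structure receiving at least each bin
#' edge. Starts at 1.0 at 0 Gy and falls to 0 beyond the maximum dose.
#'
#' @param dose 3D numeric dose (Gy).
#' @param mask 3D logical structure mask (nonempty).
#' @param bin_width_gy bin width in Gy.
#' @param geometry an [image_geometry()].
#' @param structure structure name for labelling.
#' @return An object of class `dvh_curve` with `bin_edges`, `fraction`,
#'   `cc` and `total_cc`.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.1, geometry,
                        structure = "structure") {
  check_mask(mask, geometry)
  if (!any(mask)) stop("cannot compute a DVH for an empty structure")
  d <- sort(dose[mask])
  n <- length(d)
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  # count of doses >= edge via the sorted vector
  below <- findInterval(edges * (1 - 1e-12) - 1e-12, d)
  frac <- (n - below) / n
  total <- n * voxel_volume_cc(geometry)
  structure(list(structure = structure, bin_edges = edges, fraction = frac,
                 cc = frac * total, total_cc = total), class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s (%.1f cc), %d bins to %.1f Gy\n", x$structure,
              x$total_cc, length(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Plot a cumulative DVH
#' @param x a `dvh_curve`.
#' @param ... passed to [graphics::plot()].
#' @return The curve, invisibly.
#' @export
plot.dvh_curve <- function(x, ...) {
  graphics::plot(x$bin_edges, 100 * x$fraction, type = "l",
                 xlab = "Dose (Gy)", ylab = "Volume (%)",
                 main = x$structure, ylim = c(0, 100), ...)
  invisible(x)
}

#' Dose-volume metrics
#'
#' `metric_v`: fraction/absolute volume receiving at least `x_gy`
#' (boundary convention: `>=`). `metric_dmax`: maximum voxel dose.
#' `metric_dcc`: minimum dose among the hottest `v_cc` of the structure
#' (near-max dose).
#'
#' @param dose 3D numeric dose (Gy).
#' @param mask 3D logical structure mask (nonempty).
#' @param x_gy dose level in Gy.
#' @param geometry an [image_geometry()].
#' @return `metric_v`: list with `percent` and `cc`; `metric_dmax`,
#'   `metric_dcc`: Gy.
#' @export
metric_v <- function(dose, mask, x_gy, geometry) {
  if (!any(mask)) stop("structure mask is empty")
  sel <- dose[mask] >= x_gy
  list(percent = 100 * mean(sel),
       cc = sum(sel) * voxel_volume_cc(geometry))
}

#' @rdname metric_v
#' @export
metric_dmax <- function(dose, mask) {
  if (!any(mask)) stop("structure mask is empty")
  max(dose[mask])
}

#' @rdname metric_v
#' @param v_cc hottest volume in cc (must not exceed the structure volume).
#' @export
metric_dcc <- function(dose, mask, v_cc, geometry) {
  if (!any(mask)) stop("structure mask is empty")
  tot <- volume_cc(mask, geometry)
  if (v_cc > tot)
    stop(sprintf("v_cc = %g cc exceeds the structure volume (%.2f cc)",
                 v_cc, tot))
  d <- sort(dose[mask], decreasing = TRUE)
  nvox <- max(1L, min(length(d), round(v_cc / voxel_volume_cc(geometry))))
  d[nvox]
}

embrace_rules <- function(rx) {
  hard <- data.frame(
    structure = c("bladder", "rectum", "femurs", "spinal_cord",
                  "bowel_space"),
    metric = "Dmax", x_gy = NA_real_, limit = 1.05 * rx, comparator = "<",
    severity = "hard", ruleset = "EMBRACE II hard",
    stringsAsFactors = FALSE)
  soft <- data.frame(
    structure = c("bladder", "rectum", "bladder", "rectum",
                  "bladder", "rectum", "bowel_space", "femurs"),
    metric = c("V40Gy", "V40Gy", "V30Gy", "V30Gy",
               "V45Gy", "V45Gy", "V40Gy", "V40Gy"),
    x_gy = c(40, 40, 30, 30, 45, 45, 40, 40),
    limit = c(75, 85, 85, 95, 50, 80, 30, 15),
    comparator = "<", severity = "soft",
    ruleset = c("EMBRACE II soft", "EMBRACE II soft", "EMBRACE II soft",
                "EMBRACE II soft", "internal", "internal", "internal",
                "internal"),
    stringsAsFactors = FALSE)
  rbind(hard, soft)
}

#' EMBRACE II-style constraint report
#'
#' Evaluates the hard maximum-dose constraints (Dmax < 105% of rx for
#' bladder, rectum, femurs, spinal cord and bowel) and the soft
#' dose-volume constraints (bladder V40 < 75%, V30 < 85%, V45 < 50%;
#' rectum V40 < 85%, V30 < 95%, V45 < 80%; bowel space V40 < 30%; femurs
#' V40 < 15%). Femur metrics pool left and right femur. A missing
#' structure marks its rules not-evaluable rather than silently passed.
#'
#' @param dose 3D numeric dose (Gy).
#' @param structures a `structure_set`.
#' @param rx prescription in Gy.
#' @return A data.frame of class `constraint_report`: one row per rule
#'   with `value`, `limit`, `comparator`, `severity`, `ruleset`, `pass`,
#'   `evaluable`.
#' @export
embrace_report <- function(dose, structures, rx) {
  geom <- structures$geometry
  rules <- embrace_rules(rx)
  get_mask <- function(nm) {
    if (nm == "femurs") {
      l <- structures$masks$femur_l; r <- structures$masks$femur_r
      if (is.null(l) || is.null(r)) return(NULL)
      l | r
    } else {
      structures$masks[[nm]]
    }
  }
  rows <- lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    m <- get_mask(r$structure)
    if (is.null(m) || !any(m)) {
      r$value <- NA_real_; r$pass <- NA; r$evaluable <- FALSE
      return(r)
    }
    r$value <- if (r$metric == "Dmax") metric_dmax(dose, m)
               else metric_v(dose, m, r$x_gy, geom)$percent
    r$pass <- r$value < r$limit
    r$evaluable <- TRUE
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("constraint_report", "data.frame")
  out
}

#' @export
print.constraint_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$value <- round(df$value, 2)
  df$status <- ifelse(!df$evaluable, "not evaluable",
                      ifelse(df$pass, "PASS", "FAIL"))
  print(df[, c("structure", "metric", "value", "comparator", "limit",
               "severity", "ruleset", "status")], row.names = FALSE)
  invisible(x)
}
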