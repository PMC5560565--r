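# Layer thickness maps, quadrant statistics and group comparisons.

#' The eight analyzed retinal layers
#'
#' Five inner-retinal layers (RNFGC complex, IPL, INL, combined RNFGC+IPL,
#' and the inner retina IR), two outer-retinal quantities (ONL and outer
#' retina OR) and the total retinal thickness (TRT). In light-damage mode
#' the ONL is defined from the top of the ONL to Bruch's membrane; the OR
#' lower bound is Bruch's membrane in both modes, which makes
#' `TRT = IR + OR` an exact identity.
#'
#' @param mode `"healthy"` or `"ld"`.
#' @return data frame with columns `layer`, `upper`, `lower`.
#' @export
layer_definitions <- function(mode = c("healthy", "ld")) {
  mode <- match.arg(mode)
  onl <- if (mode == "healthy") c("OPL-ONL", "ELM") else c("ONL-Top", "BM")
  data.frame(
    layer = c("RNFGC", "IPL", "INL", "RNFGC+IPL", "IR", "ONL", "OR", "TRT"),
    upper = c("ILM", "RNFGC-IPL", "IPL-INL", "ILM", "ILM", onl[1], "INL-OPL", "ILM"),
    lower = c("RNFGC-IPL", "IPL-INL", "INL-OPL", "IPL-INL", "INL-OPL", onl[2], "BM", "BM"),
    stringsAsFactors = FALSE
  )
}

#' En-face thickness maps of the eight analyzed layers
#'
#' Thickness is `(lower - upper) * axial spacing` per column, in um.
#'
#' @param surfaces a [surface_set()] in voxel units with all surfaces of
#'   the mode present.
#' @param spacing voxel spacing in um (`z` component used).
#' @param mode `"healthy"` or `"ld"`.
#' @return named list of eight `B x X` matrices (um).
#' @export
thickness_maps <- function(surfaces, spacing, mode = c("healthy", "ld")) {
  mode <- match.arg(mode)
  stopifnot(inherits(surfaces, "surface_set"))
  defs <- layer_definitions(mode)
  missing <- setdiff(unique(c(defs$upper, defs$lower)), names(surfaces$surfaces))
  if (length(missing))
    stop("missing surface(s) required for thickness maps: ",
         paste(missing, collapse = ", "))
  sz <- spacing[3]
  out <- lapply(seq_len(nrow(defs)), function(i)
    (surfaces$surfaces[[defs$lower[i]]] - surfaces$surfaces[[defs$upper[i]]]) * sz)
  names(out) <- defs$layer
  if (any(vapply(out, min, 0) < -1e-6))
    stop("negative thickness encountered; surfaces violate ordering")
  lapply(out, function(m) pmax(m, 0))
}

#' Quadrant statistics of an en-face map
#'
#' The analysis annulus (diameters `d_inner_mm` to `d_outer_mm`) is split
#' into superior (S), inferior (I), nasal (N) and temporal (T) wedges by
#' the +/- 45 degree diagonals, and the mean and SD of the map are
#' computed per wedge. With the default orientation the superior wedge is
#' at the top of the en-face image (decreasing b) and the nasal wedge at
#' increasing x; the labelling is configurable because it depends on the
#' eye and scan orientation. `"superior-down"` rotates the convention by
#' 180 degrees, swapping S with I and N with T.
#'
#' @param map numeric `B x X` en-face map (e.g. a thickness map, um).
#' @param spacing voxel spacing in um (`x`, `y` components used).
#' @param center en-face centre `(b, x)`, default the grid centre.
#' @param d_inner_mm,d_outer_mm annulus diameters (mm).
#' @param orientation `"superior-up"` (default) or `"superior-down"`.
#' @return data frame with columns `quadrant`, `n_px`, `mean`, `sd`.
#' @export
quadrant_stats <- function(map, spacing, center = NULL,
                           d_inner_mm = 0.3, d_outer_mm = 1.2,
                           orientation = c("superior-up", "superior-down")) {
  orientation <- match.arg(orientation)
  B <- nrow(map); X <- ncol(map)
  mask <- make_eval_mask(c(B, X), spacing, center, d_inner_mm, d_outer_mm)
  if (is.null(center)) center <- attr(mask, "center")
  bb <- matrix(seq_len(B) - 1 - center[1], B, X) * spacing[2]
  xx <- matrix(seq_len(X) - 1 - center[2], B, X, byrow = TRUE) * spacing[1]
  theta <- atan2(-bb, xx)  # +90 deg = decreasing b = image top
  deg <- theta * 180 / pi
  wedge <- ifelse(deg > -45 & deg <= 45, "E",
                  ifelse(deg > 45 & deg <= 135, "U",
                         ifelse(deg > -135 & deg <= -45, "D", "W")))
  labels <- if (orientation == "superior-up")
    c(U = "S", D = "I", E = "N", W = "T")
  else
    c(U = "I", D = "S", E = "T", W = "N")
  quad <- matrix(labels[wedge], B, X)
  out <- lapply(c("S", "I", "N", "T"), function(q) {
    sel <- mask & quad == q
    if (!any(sel)) stop("empty quadrant wedge: ", q)
    v <- map[sel]
    if (anyNA(v) || any(!is.finite(v))) stop("map must be finite inside the annulus")
    data.frame(quadrant = q, n_px = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.paired_t <- function(da, db) {
  d <- da - db
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  sdd <- stats::sd(d)
  if (sdd < 1e-12) {
    if (abs(mean(d)) < 1e-12) {
      warning("identical paired values; returning p = 1")
      return(c(t = 0, df = n - 1, p = 1))
    }
    return(c(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  tt <- stats::t.test(da, db, paired = TRUE)
  c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Compare layer thicknesses between two cohorts
#'
#' Runs a t-test per (layer, day, quadrant) combination present in both
#' cohorts, pairing observations by eye index (the published analysis used
#' paired tests; an unpaired two-sample option is provided since the
#' pairing of independent animals is a reporting convention). No
#' multiple-testing correction is applied; significance is `p < alpha`
#' with `alpha = 0.01` by default.
#'
#' @param cohort_a,cohort_b long data frames as produced by
#'   [generate_cohort()] (columns `eye`, `day`, `layer`, `quadrant`,
#'   `thickness_um`; `quadrant`/`day` optional).
#' @param alpha significance level.
#' @param paired pair by eye order within each stratum (requires equal n).
#' @param match_days require equal `day` in both cohorts (set `FALSE` for
#'   longitudinal contrasts such as day 1 vs day 6 within a group).
#' @return data frame with one row per stratum: group means, `t`, `df`,
#'   `p`, `significant`.
#' @export
group_compare <- function(cohort_a, cohort_b, alpha = 0.01, paired = TRUE,
                          match_days = TRUE) {
  keys <- intersect(c("layer", "quadrant", if (match_days) "day"),
                    intersect(names(cohort_a), names(cohort_b)))
  if (!"layer" %in% keys) stop("cohorts must have a `layer` column")
  ka <- interaction(cohort_a[keys], drop = TRUE)
  kb <- interaction(cohort_b[keys], drop = TRUE)
  strata <- intersect(levels(ka), levels(kb))
  rows <- list()
  for (s in strata) {
    a <- cohort_a[ka == s, ]
    b <- cohort_b[kb == s, ]
    a <- a[order(a$eye), ]; b <- b[order(b$eye), ]
    if (paired && nrow(a) != nrow(b))
      stop("paired comparison undefined: unequal group sizes in stratum ", s)
    if (paired) {
      r <- .paired_t(a$thickness_um, b$thickness_um)
    } else {
      tt <- stats::t.test(a$thickness_um, b$thickness_um)
      r <- c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
    meta <- a[1, keys, drop = FALSE]
    rownames(meta) <- NULL
    rows[[length(rows) + 1L]] <- cbind(
      meta,
      data.frame(n = nrow(a), mean_a = mean(a$thickness_um),
                 mean_b = mean(b$thickness_um),
                 t = r[["t"]], df = r[["df"]], p = r[["p"]],
                 significant = r[["p"]] < alpha)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
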