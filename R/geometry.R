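#' Derive the spine/dendrite geometry from a configuration
#'
#' The spine head is a hemisphere of volume `head_volume`, so its radius is
#' `(3 V / 2 pi)^(1/3)`; the synaptic cleft is a flat cylinder of the same
#' radius between the head and the presynaptic terminal.  The head is split
#' into a PSD compartment (a fraction `psd_volume_fraction` of the head
#' volume) and the remaining cytosol; the neck and shaft are cylinders.
#'
#' The derived surface-to-volume ratios must lie inside the validity ranges
#' of the calcium-handling calibration data (4-20 per um for the spine, 1-4
#' per um for the shaft); geometries outside are rejected unless
#' `force = TRUE`.
#'
#' @param config a [spine_config()] object (or its `$geometry` list).
#' @param force skip the surface-to-volume validity check.
#' @return A tibble with one row per named geometric quantity (`quantity`,
#'   `value`, `unit`), carrying the full geometry as attribute `"geometry"`.
#' @export
#' @examples
#' derive_geometry(spine_config())
derive_geometry <- function(config, force = FALSE) {
  g <- if (!is.null(config$geometry)) config$geometry else config
  if (g$head_volume <= 0) stop("head_volume must be positive", call. = FALSE)

  head_radius <- (3 * g$head_volume / (2 * pi))^(1 / 3)   # um
  cleft_radius <- head_radius
  psd_volume <- g$psd_volume_fraction * g$head_volume
  cyt_volume <- g$head_volume - psd_volume
  neck_volume <- pi * g$neck_radius^2 * g$neck_length
  shaft_volume <- pi * g$shaft_radius^2 * g$shaft_length

  head_area <- 2 * pi * head_radius^2          # curved hemisphere surface
  psd_area <- pi * g$psd_outer_radius^2        # synaptic face under the PSD
  neck_area <- 2 * pi * g$neck_radius * g$neck_length
  shaft_area <- 2 * pi * g$shaft_radius * g$shaft_length

  sv_spine <- head_area / g$head_volume
  sv_shaft <- shaft_area / shaft_volume
  if (!force) {
    if (sv_spine < 4 || sv_spine > 20)
      stop("spine surface-to-volume ratio ", signif(sv_spine, 3),
           " outside calibration validity range 4-20 /um (use force = TRUE)",
           call. = FALSE)
    if (sv_shaft < 1 || sv_shaft > 4)
      stop("shaft surface-to-volume ratio ", signif(sv_shaft, 3),
           " outside calibration validity range 1-4 /um (use force = TRUE)",
           call. = FALSE)
  }

  geom <- list(
    head_volume = g$head_volume, head_radius = head_radius,
    cleft_height = g$cleft_height, cleft_radius = cleft_radius,
    psd_outer_radius = g$psd_outer_radius,
    perisynaptic_outer_radius = g$perisynaptic_outer_radius,
    psd_volume_fraction = g$psd_volume_fraction,
    psd_volume = psd_volume, cyt_volume = cyt_volume,
    neck_length = g$neck_length, neck_radius = g$neck_radius,
    neck_volume = neck_volume,
    shaft_radius = g$shaft_radius, shaft_length = g$shaft_length,
    shaft_volume = shaft_volume,
    head_area = head_area, psd_area = psd_area,
    neck_area = neck_area, shaft_area = shaft_area,
    sv_spine = sv_spine, sv_shaft = sv_shaft
  )

  out <- tibble::tibble(
    quantity = c("head_radius_nm", "cleft_radius_nm", "psd_volume_um3",
                 "cyt_volume_um3", "neck_volume_um3", "shaft_volume_um3",
                 "sv_spine_per_um", "sv_shaft_per_um"),
    value = c(head_radius * 1e3, cleft_radius * 1e3, psd_volume, cyt_volume,
              neck_volume, shaft_volume, sv_spine, sv_shaft),
    unit = c("nm", "nm", "um^3", "um^3", "um^3", "um^3", "1/um", "1/um")
  )
  attr(out, "geometry") <- geom
  out
}

# internal: plain geometry list
.geom <- function(config, force = FALSE) attr(derive_geometry(config, force), "geometry")

#' Classify a radial distance into a membrane zone
#'
#' Distances are measured from the centre of the postsynaptic surface.
#' The synaptic (PSD) zone spans (0, 150] nm, the perisynaptic annulus
#' (150, 365] nm, and everything beyond is extrasynaptic.  Boundaries are
#' half-open below and closed above.
#'
#' @param radial_distance distance(s) in nm, non-negative.
#' @param config optional [spine_config()] supplying the zone boundaries.
#' @return Character vector: `"synaptic"`, `"perisynaptic"` or `"extrasynaptic"`.
#' @export
#' @examples
#' zone_of(c(100, 150, 500))
zone_of <- function(radial_distance, config = spine_config()) {
  if (any(radial_distance < 0)) stop("radial distance must be non-negative", call. = FALSE)
  psd <- config$geometry$psd_outer_radius * 1e3
  peri <- config$geometry$perisynaptic_outer_radius * 1e3
  ifelse(radial_distance <= psd, "synaptic",
         ifelse(radial_distance <= peri, "perisynaptic", "extrasynaptic"))
}
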