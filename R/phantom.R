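# Synthetic high-frequency ultrasound (HFUS) skin phantoms.
#
# Phantoms emulate the axial anatomy of a 75 MHz skin scan, top to bottom:
# a bright probe-membrane line, dark coupling gel, a bright (gently
# undulating) epidermis band, an optional dark subepidermal low echogenic
# band (SLEB), speckled dermis with an optional hypoechoic tumour disk, and
# a deeper muscle zone. Four classes are generated: atopic dermatitis (AD,
# thick SLEB), psoriasis (thickened epidermis, thinner SLEB), skin tumour
# (hypoechoic disk in the dermis) and control (none of these).

PHANTOM_CLASSES <- c("AD", "psoriasis", "tumor", "control")

# region codes of the internal region map
REGION <- c(gel = 1L, membrane = 2L, epidermis = 3L, sleb = 4L,
            dermis = 5L, tumor = 6L, muscle = 7L)

#' Specify a synthetic skin phantom
#'
#' Returns a validated specification for [generate_phantom()]. Defaults give
#' a 256 x 256 grid at 0.02 mm/px axially, so the roughly 2 mm of
#' diagnostically relevant tissue below the epidermis spans about 100 rows.
#'
#' @param class_label one of `"AD"`, `"psoriasis"`, `"tumor"`, `"control"`.
#' @param height_px,width_px grid size in pixels.
#' @param lateral_res,axial_res pixel size in mm (columns / rows).
#' @param epidermis_top_mm mean depth of the epidermis top boundary.
#' @param epidermis_thickness_mm epidermis band thickness. For psoriasis the
#'   default is thickened by a factor of 1.8 relative to the other classes.
#' @param undulation_mm,undulation_periods amplitude (mm) and number of
#'   lateral periods of the sinusoidal epidermis boundary.
#' @param sleb_thickness_mm thickness of the SLEB (AD and psoriasis only;
#'   must be 0 for the other classes).
#' @param tumor_center_mm,tumor_radius_mm tumour disk centre
#'   `c(depth_below_epidermis, lateral)` in mm and radius in mm (tumour
#'   class only).
#' @param membrane_depth_mm depth of the probe membrane line.
#' @param skin_depth_mm extent of dermis below the epidermis before the
#'   muscle zone starts.
#' @param intensity named numeric vector of noiseless region intensities in
#'   `[0, 1]`; must satisfy membrane > epidermis > dermis > sleb >= gel.
#' @param speckle_scale multiplicative speckle strength in `[0, 1]`:
#'   0 is noiseless, 1 full Rayleigh speckle.
#' @param undulation_phase phase of the epidermis undulation (radians).
#' @param seed integer seed for the speckle field.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("control", "AD", "psoriasis", "tumor"),
                         height_px = 256L, width_px = 256L,
                         lateral_res = 0.02, axial_res = 0.02,
                         epidermis_top_mm = 1.0,
                         epidermis_thickness_mm = NULL,
                         undulation_mm = 0.1,
                         undulation_periods = 2,
                         sleb_thickness_mm = NULL,
                         tumor_center_mm = NULL,
                         tumor_radius_mm = 0.6,
                         membrane_depth_mm = 0.15,
                         skin_depth_mm = 2.0,
                         intensity = c(membrane = 0.95, gel = 0.05,
                                       epidermis = 0.85, sleb = 0.15,
                                       dermis = 0.55, tumor = 0.20,
                                       muscle = 0.35),
                         speckle_scale = 0.6,
                         undulation_phase = 0,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  if (is.null(epidermis_thickness_mm))
    epidermis_thickness_mm <- if (class_label == "psoriasis") 0.3 * 1.8 else 0.3
  if (is.null(sleb_thickness_mm))
    sleb_thickness_mm <- switch(class_label, AD = 0.5, psoriasis = 0.2, 0)
  if (class_label %in% c("tumor", "control") && sleb_thickness_mm > 0)
    stop("sleb_thickness_mm must be 0 for class ", class_label)
  if (class_label == "tumor" && is.null(tumor_center_mm))
    tumor_center_mm <- c(1.0, width_px * lateral_res / 2)
  if (class_label != "tumor") tumor_center_mm <- NULL
  stopifnot(height_px >= 8, width_px >= 8, lateral_res > 0, axial_res > 0,
            epidermis_top_mm > 0, epidermis_thickness_mm > 0,
            sleb_thickness_mm >= 0, speckle_scale >= 0, speckle_scale <= 1)
  need <- c("membrane", "gel", "epidermis", "sleb", "dermis", "tumor", "muscle")
  if (!all(need %in% names(intensity)))
    stop("intensity must name all regions: ", paste(need, collapse = ", "))
  if (!(intensity["membrane"] > intensity["epidermis"] &&
        intensity["epidermis"] > intensity["dermis"] &&
        intensity["dermis"] > intensity["sleb"] &&
        intensity["sleb"] >= intensity["gel"]))
    stop("region intensities must satisfy membrane > epidermis > dermis > sleb >= gel")
  depth_mm <- height_px * axial_res
  need_mm <- epidermis_top_mm + undulation_mm + epidermis_thickness_mm +
    sleb_thickness_mm + skin_depth_mm
  if (need_mm > depth_mm)
    stop(sprintf(paste0("phantom geometry does not fit the grid: ",
                        "%.2f mm of structure vs %.2f mm of depth ",
                        "(height_px * axial_res)"), need_mm, depth_mm))
  if (membrane_depth_mm + 0.1 >= epidermis_top_mm - undulation_mm)
    stop("membrane must lie strictly above the epidermis band")
  structure(list(class_label = class_label, height_px = as.integer(height_px),
                 width_px = as.integer(width_px), lateral_res = lateral_res,
                 axial_res = axial_res, epidermis_top_mm = epidermis_top_mm,
                 epidermis_thickness_mm = epidermis_thickness_mm,
                 undulation_mm = undulation_mm,
                 undulation_periods = undulation_periods,
                 sleb_thickness_mm = sleb_thickness_mm,
                 tumor_center_mm = tumor_center_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 membrane_depth_mm = membrane_depth_mm,
                 skin_depth_mm = skin_depth_mm, intensity = intensity,
                 speckle_scale = speckle_scale,
                 undulation_phase = undulation_phase, seed = as.integer(seed)),
            class = "phantom_spec")
}

mm_to_rows <- function(mm, axial_res) as.integer(round(mm / axial_res))

# Region map construction: per column, bands are stacked by row counts so
# that band thicknesses in pixels are round(mm / axial_res) exactly.
phantom_region_map <- function(spec) {
  h <- spec$height_px; w <- spec$width_px
  region <- matrix(REGION[["gel"]], h, w)
  mem_row <- max(1L, mm_to_rows(spec$membrane_depth_mm, spec$axial_res))
  mem_thick <- max(1L, mm_to_rows(0.1, spec$axial_res))
  region[mem_row:min(h, mem_row + mem_thick - 1L), ] <- REGION[["membrane"]]
  cols <- seq_len(w)
  und <- spec$undulation_mm *
    sin(2 * pi * spec$undulation_periods * (cols - 1) / w + spec$undulation_phase)
  top <- mm_to_rows(spec$epidermis_top_mm + und, spec$axial_res) + 1L
  n_epi <- mm_to_rows(spec$epidermis_thickness_mm, spec$axial_res)
  n_sleb <- mm_to_rows(spec$sleb_thickness_mm, spec$axial_res)
  n_skin <- mm_to_rows(spec$skin_depth_mm, spec$axial_res)
  R <- matrix(seq_len(h), h, w)
  TOP <- matrix(top, h, w, byrow = TRUE)
  epi <- R >= TOP & R < TOP + n_epi
  sleb <- R >= TOP + n_epi & R < TOP + n_epi + n_sleb
  dermis <- R >= TOP + n_epi + n_sleb & R < TOP + n_epi + n_sleb + n_skin
  muscle <- R >= TOP + n_epi + n_sleb + n_skin
  region[muscle] <- REGION[["muscle"]]
  region[dermis] <- REGION[["dermis"]]
  region[sleb] <- REGION[["sleb"]]
  region[epi] <- REGION[["epidermis"]]
  if (spec$class_label == "tumor") {
    epi_bottom_mid <- (top[floor(w / 2)] + n_epi + n_sleb - 1L) * spec$axial_res
    cy <- epi_bottom_mid + spec$tumor_center_mm[1]
    cx <- spec$tumor_center_mm[2]
    DY <- (R - 0.5) * spec$axial_res - cy
    DX <- (matrix(cols, h, w, byrow = TRUE) - 0.5) * spec$lateral_res - cx
    disk <- DY^2 + DX^2 <= spec$tumor_radius_mm^2
    region[disk & region == REGION[["dermis"]]] <- REGION[["tumor"]]
  }
  region
}

#' Generate one synthetic HFUS phantom
#'
#' Draws the region map for `spec`, paints the noiseless intensities, applies
#' multiplicative Rayleigh-like speckle, and returns the image together with
#' the ground-truth epidermis mask. Deterministic for a fixed spec (the
#' speckle field is seeded from `spec$seed`).
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom_sample` with elements `image` (numeric
#'   matrix in `[0, 1]`), `mask` (logical matrix, the epidermis pixels),
#'   `label`, `patient_id` (`NA` until assigned by [generate_dataset()]),
#'   `lateral_res`, `axial_res`, and `region` (the integer region map).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  region <- phantom_region_map(spec)
  img <- matrix(unname(spec$intensity[names(REGION)[region]]),
                spec$height_px, spec$width_px)
  mask <- region == REGION[["epidermis"]]
  if (!any(mask)) stop("degenerate spec: empty epidermis band")
  if (spec$speckle_scale > 0) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(spec$seed)
    # Rayleigh field with unit mean: sigma = 1 / sqrt(pi / 2)
    ray <- sqrt(-2 * log(stats::runif(length(img)))) / sqrt(pi / 2)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    noise <- (1 - spec$speckle_scale) + spec$speckle_scale * ray
    img <- clamp01(img * matrix(noise, nrow(img)))
  }
  structure(list(image = img, mask = mask, label = spec$class_label,
                 patient_id = NA_character_, lateral_res = spec$lateral_res,
                 axial_res = spec$axial_res, region = region, spec = spec),
            class = "phantom_sample")
}

#' Generate a labelled phantom dataset with patient structure
#'
#' Generates `n_per_class` phantoms for each of the four classes, assigned to
#' `n_patients_per_class` patients per class. Each patient carries a random
#' offset on thickness and depth parameters, so images of one patient are
#' correlated — this is what makes patient-wise cross-validation meaningful.
#'
#' @param n_per_class images per class.
#' @param n_patients_per_class patients per class
#'   (`<= n_per_class`; images are spread evenly over patients).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param ... further arguments passed to [phantom_spec()] (e.g. a smaller
#'   `height_px` for quick experiments).
#' @return a list with `samples` (list of `phantom_sample`) and `manifest`
#'   (a tibble with columns `id`, `label`, `patient_id`, `lateral_res_mm`,
#'   `axial_res_mm`).
#' @export
generate_dataset <- function(n_per_class, n_patients_per_class, seed = 1L, ...) {
  stopifnot(n_per_class >= n_patients_per_class, n_patients_per_class >= 1)
  set.seed(seed)
  samples <- list()
  rows <- list()
  idx <- 0L
  for (cl in PHANTOM_CLASSES) {
    pat_ids <- sprintf("%s_pat%02d", cl, seq_len(n_patients_per_class))
    # even spread of images over patients
    owner <- rep(pat_ids, length.out = n_per_class)
    pat_fx <- lapply(seq_len(n_patients_per_class), function(i)
      list(thick_mult = exp(stats::rnorm(1, 0, 0.12)),
           sleb_mult = exp(stats::rnorm(1, 0, 0.15)),
           top_shift = stats::rnorm(1, 0, 0.1)))
    names(pat_fx) <- pat_ids
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      fx <- pat_fx[[owner[i]]]
      base <- phantom_spec(class_label = cl, ...)
      args <- list(...)
      args$class_label <- cl
      args$epidermis_thickness_mm <-
        base$epidermis_thickness_mm * fx$thick_mult * exp(stats::rnorm(1, 0, 0.05))
      args$sleb_thickness_mm <-
        if (base$sleb_thickness_mm > 0)
          base$sleb_thickness_mm * fx$sleb_mult * exp(stats::rnorm(1, 0, 0.05))
        else 0
      args$epidermis_top_mm <-
        max(0.5, base$epidermis_top_mm + fx$top_shift + stats::rnorm(1, 0, 0.03))
      args$undulation_phase <- stats::runif(1, 0, 2 * pi)
      args$seed <- sample.int(.Machine$integer.max, 1)
      spec <- do.call(phantom_spec, args)
      s <- generate_phantom(spec)
      s$patient_id <- owner[i]
      s$id <- sprintf("%s_%03d", cl, i)
      samples[[idx]] <- s
      rows[[idx]] <- tibble::tibble(id = s$id, label = cl,
                                    patient_id = owner[i],
                                    lateral_res_mm = s$lateral_res,
                                    axial_res_mm = s$axial_res)
    }
  }
  list(samples = samples, manifest = dplyr::bind_rows(rows))
}

#' Write a phantom dataset to disk
#'
#' Writes images as 16-bit grayscale PNG, masks as binary PNG, and the
#' manifest as CSV with columns
#' `file,mask,label,patient_id,lateral_res_mm,axial_res_mm`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest tibble with `file`/`mask` paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$file <- file.path(dir, paste0(man$id, ".png"))
  man$mask <- file.path(dir, paste0(man$id, "_mask.png"))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    EBImage::writeImage(t(s$image), man$file[i], bits.per.sample = 16L)
    png::writePNG(matrix(as.numeric(s$mask), nrow(s$mask)), man$mask[i])
  }
  out <- man[, c("file", "mask", "label", "patient_id",
                 "lateral_res_mm", "axial_res_mm")]
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
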