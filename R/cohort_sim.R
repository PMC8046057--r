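#' Simulate a control/case tooth cohort end-to-end
#'
#' Generates control and case tooth phantoms, runs the full per-tooth pipeline
#' ([analyze_tooth()]) on each, and assembles a [cohort_table()]. Case teeth
#' carry multiplicative effects on dentin density, interglobular void fraction
#' and cementum thickness relative to the control specification — the
#' characteristic hard-tissue phenotype of a mineralization disorder (reduced
#' dentin density, expanded interglobular dentin, thinned acellular cementum).
#'
#' Between-tooth biological variability is modelled as Gaussian jitter of the
#' nominal dentin density (SD `dentin_density_sd`, mg/cm^3 HA) on top of the
#' within-scan grey noise of the base specification.
#'
#' @param n_control,n_case Teeth per group.
#' @param base_spec Control [phantom_spec()]; its `void_fraction` and
#'   `noise_sd` should describe a control tooth. The default control cementum
#'   (160 um) keeps the halved case sheath (80 um) above the resolution floor
#'   of the kernel-11 filter-and-mask-back procedure (~half the kernel, 55 um
#'   at 10 um voxels), inside which cementum thickness is measurable at all.
#' @param dentin_density_ratio,void_fraction_ratio,cementum_thickness_ratio
#'   Case-over-control effect sizes.
#' @param dentin_density_sd Between-tooth SD of nominal dentin density.
#' @param seed Integer seed driving tooth seeds and jitter.
#' @param teeth_per_patient Teeth are assigned to patients in blocks of this
#'   size.
#' @return A [cohort_table()] with one row per tooth x metric; the generating
#'   truth (per-tooth specs) is attached as attribute `truth`.
#' @export
simulate_cohort <- function(n_control = 5L, n_case = 5L,
                            base_spec = phantom_spec(void_fraction = 0.005,
                                                     noise_sd = 50,
                                                     cementum_thickness_um = 160),
                            dentin_density_ratio = 0.9,
                            void_fraction_ratio = 10,
                            cementum_thickness_ratio = 0.5,
                            dentin_density_sd = 10,
                            seed = 1L,
                            teeth_per_patient = 1L) {
  groups <- c(rep("control", n_control), rep("case", n_case))
  n <- length(groups)
  jitter <- with_seed(seed, rnorm(n, 0, dentin_density_sd))
  rows <- vector("list", n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    is_case <- groups[i] == "case"
    sp <- base_spec
    sp$density_dentin <- base_spec$density_dentin *
      (if (is_case) dentin_density_ratio else 1) + jitter[i]
    if (is_case) {
      sp$void_fraction <- base_spec$void_fraction * void_fraction_ratio
      sp$cementum_thickness_um <- base_spec$cementum_thickness_um *
        cementum_thickness_ratio
    }
    sp$seed <- as.integer(seed * 1000L + i)
    specs[[i]] <- sp
    ph <- generate_tooth_phantom(sp)
    cv <- calibrated_volume(ph$volume, sp$voxel_size_um,
                            provenance = sprintf("simulated tooth %d", i))
    res <- analyze_tooth(cv, tooth_id = sprintf("%s_%02d", groups[i], i),
                         measure_root_dentin_thickness = FALSE)
    res$patient <- sprintf("P%02d", (i - 1L) %/% teeth_per_patient + 1L)
    res$group <- groups[i]
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  out <- out[, c("patient", "tooth", "group", "metric", "value")]
  tb <- cohort_table(out)
  attr(tb, "truth") <- list(specs = specs, groups = groups,
                            dentin_density_ratio = dentin_density_ratio,
                            void_fraction_ratio = void_fraction_ratio,
                            cementum_thickness_ratio = cementum_thickness_ratio)
  tb
}
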