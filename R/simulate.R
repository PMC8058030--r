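#' Simulate a phantom cohort on disk
#'
#' Generates paired reference/candidate volumes, structure masks and
#' (optionally) toy dose grids for several seeded phantoms, writes them as
#' NIfTI under \code{outputDir} plus a JSON manifest, and returns a patient
#' list ready to drop into a [runEvaluation()] configuration.
#'
#' @param outputDir directory to write into (created if needed).
#' @param nPhantoms number of phantoms (default 5).
#' @param seed base seed; phantom i uses seed + i for the anatomy and the
#'   perturbation.
#' @param spec a [phantomSpec()] template (its seed is overridden per
#'   phantom).
#' @param perturbation a [perturbationSpec()] template (seed overridden
#'   per phantom).
#' @param writeDose also compute and write toy dose grids (default FALSE;
#'   [runEvaluation()] computes them on the fly when absent).
#' @param beams a [toyBeamSpec()] for \code{writeDose}.
#' @return list of per-patient config entries (id, ct, sct, masks, roles).
#' @export
simulateCohort <- function(outputDir, nPhantoms = 5L, seed = 1L,
                           spec = phantomSpec(),
                           perturbation = perturbationSpec(),
                           writeDose = FALSE, beams = toyBeamSpec()) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  roles <- c(body = "body", ptv_t = "ptv_t", ptv_n = "ptv_n",
             prv_spinal_cord = "serial_oar", parotid_sin = "parallel_oar",
             parotid_dx = "parallel_oar", larynx = "parallel_oar")
  patients <- list()
  manifest <- list()
  for (i in seq_len(nPhantoms)) {
    id <- sprintf("phantom%02d", i)
    pdir <- file.path(outputDir, id)
    dir.create(pdir, showWarnings = FALSE)
    spec$seed <- as.integer(seed + i)
    perturbation$seed <- as.integer(seed + i)
    ph <- generatePhantom(spec)
    sct <- perturbToSct(ph$ct, ph$truth, perturbation)

    ctPath <- file.path(pdir, "ct.nii.gz")
    sctPath <- file.path(pdir, "sct.nii.gz")
    writeVolume(ph$ct, ctPath)
    writeVolume(sct, sctPath)
    maskPaths <- list()
    for (nm in names(ph$masks)) {
      mp <- file.path(pdir, paste0(nm, ".nii.gz"))
      writeVolume(ph$masks[[nm]], mp)
      maskPaths[[nm]] <- mp
    }
    entry <- list(id = id, ct = ctPath, sct = sctPath, masks = maskPaths,
                  roles = as.list(roles),
                  excluded_slices = as.list(ph$streakSlices))
    if (writeDose) {
      dp <- toyDosePair(ph$ct, sct, beams = beams,
                        targetPoint = maskCentroid(ph$masks$ptv_t),
                        body = ph$masks$body)
      entry$dose_ref <- file.path(pdir, "dose_ct.nii.gz")
      entry$dose_cand <- file.path(pdir, "dose_sct.nii.gz")
      writeVolume(dp$ref, entry$dose_ref)
      writeVolume(dp$cand, entry$dose_cand)
    }
    patients[[id]] <- entry
    manifest[[id]] <- list(seed = spec$seed,
                           region_slices = as.list(ph$regionSlices),
                           grid = spec$dim, spacing_mm = spec$spacing)
  }
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  patients
}
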