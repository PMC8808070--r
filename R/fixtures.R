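## Bundled example spin systems for the signal-giving species of a
## menaquinone-linked formate dehydrogenase, plus the Mn(II) field
## marker. g-values and the proton hyperfine tensor are the published
## spin-Hamiltonian parameters; the per-axis linewidths are synthetic
## placeholders (the published per-axis widths are not reproduced
## here), except the semiquinone H-strain width, which is calibrated
## once so the simulated X-band peak-to-peak linewidth matches the
## observed 0.88 mT.

#' Example spin systems
#'
#' A named list of \linkS4class{SpinSystem} fixtures:
#' \describe{
#'   \item{moV}{Mo(V) active-site species, g = 1.9971/1.9933/1.9890
#'     with one strongly coupled proton, A = 13/13/11 MHz (H-strain,
#'     X-band width: narrow enough that the proton doublet is
#'     resolved).}
#'   \item{moVWband}{the same Mo(V) species with the broader effective
#'     H-strain width appropriate at W band, where unresolved strain
#'     contributions dominate and the proton structure is washed out
#'     (per-spectrum linewidths, as is standard in multifrequency
#'     simulation).}
#'   \item{msk}{protein-bound menasemiquinone radical,
#'     g = 2.0054/2.0051/2.0023 (H-strain, width calibrated to a
#'     0.88 mT X-band peak-to-peak linewidth).}
#'   \item{fe2s2}{axial [2Fe-2S]1+ cluster, g = 2.020/2.020/1.939
#'     (g-strain).}
#'   \item{fe4s4Slow1}{slow-relaxing [4Fe-4S]1+ cluster of enzyme 1,
#'     g = 2.047/1.948/1.897 (g-strain).}
#'   \item{fe4s4Slow2}{slow-relaxing [4Fe-4S]1+ cluster of enzyme 2,
#'     g = 2.030/1.940/1.912 (g-strain).}
#'   \item{mnMarker}{Mn(II) field marker, isotropic g = 2.00101 with
#'     I = 5/2 and a = -8.710 mT (-243.95 MHz).}
#' }
#' Linewidths other than the semiquinone's are synthetic placeholders
#' chosen to give well-resolved features at X band.
#'
#' @return Named list of \linkS4class{SpinSystem} objects.
#' @examples
#' names(exampleSpinSystems())
#' @export
exampleSpinSystems <- function() {
  list(
    moV = spinSystem(c(1.9971, 1.9933, 1.9890),
                     hyperfine(c(13, 13, 11), nuclearSpin = 0.5),
                     lwMode = "H_strain", lwWidths = 0.30,
                     label = "Mo(V)"),
    moVWband = spinSystem(c(1.9971, 1.9933, 1.9890),
                          hyperfine(c(13, 13, 11), nuclearSpin = 0.5),
                          lwMode = "H_strain", lwWidths = 1.4,
                          label = "Mo(V) (W band)"),
    msk = spinSystem(c(2.0054, 2.0051, 2.0023),
                     lwMode = "H_strain", lwWidths = 0.9712,
                     label = "MSK"),
    fe2s2 = spinSystem(c(2.020, 2.020, 1.939),
                       lwMode = "g_strain",
                       lwWidths = c(0.008, 0.008, 0.010),
                       label = "[2Fe-2S]"),
    fe4s4Slow1 = spinSystem(c(2.047, 1.948, 1.897),
                            lwMode = "g_strain",
                            lwWidths = c(0.015, 0.015, 0.018),
                            label = "[4Fe-4S] slow (enzyme 1)"),
    fe4s4Slow2 = spinSystem(c(2.030, 1.940, 1.912),
                            lwMode = "g_strain",
                            lwWidths = c(0.015, 0.015, 0.018),
                            label = "[4Fe-4S] slow (enzyme 2)"),
    mnMarker = spinSystem(rep(2.00101, 3),
                          hyperfine(-8.710 * 2.00101 * 13.9962,
                                    nuclearSpin = 2.5),
                          lwMode = "H_strain", lwWidths = 0.5,
                          label = "Mn(II) marker")
  )
}
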