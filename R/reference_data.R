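#' Published reference plane normals of the left inner ear
#'
#' Unit normal vectors (quoted to 4 decimals) of the crista ampullaris
#' (`_CA`), membranous canal (`_MEM`) and bony canal (`_BONY`) planes of the
#' left posterior (LPC), lateral (LHC) and anterior/superior (LAC)
#' semicircular canals, expressed in the standardized head frame (X right,
#' Y forward, Z up). These published measurements seed the synthetic
#' generator's default geometry and serve as the package's worked examples;
#' they are reference values, not an anatomical ground truth for any
#' individual.
#'
#' @return data frame with columns `label`, `A`, `B`, `C`.
#' @export
reference_normals <- function() {
  data.frame(
    label = c("LPC_CA", "LHC_CA", "LAC_CA",
              "LPC_MEM", "LPC_BONY", "LHC_MEM", "LHC_BONY",
              "LAC_MEM", "LAC_BONY"),
    A = c(-0.747, 0.9723, 0.5364, 0.6229, 0.6553, -0.018, -0.0049,
          -0.7526, -0.7716),
    B = c(-0.1077, -0.1052, -0.0841, -0.7016, -0.6709, 0.3302, 0.3305,
          -0.5924, -0.5643),
    C = c(-0.6562, -0.2087, -0.8397, -0.346, -0.3472, -0.9437, -0.9438,
          -0.2874, -0.2936))
}

#' Look up one reference normal
#'
#' @param label row label of [reference_normals()], e.g. `"LHC_CA"`.
#' @return length-3 numeric normal (as printed; not renormalized).
#' @export
reference_normal <- function(label) {
  tab <- reference_normals()
  i <- match(label, tab$label)
  if (is.na(i)) stop("unknown reference label: ", label, call. = FALSE)
  as.numeric(tab[i, c("A", "B", "C")])
}
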