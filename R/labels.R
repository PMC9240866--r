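#' 88-region AAL-style atlas labels
#'
#' Region labels for the 88-region cortical/subcortical parcellation used by
#' default throughout the package: the AAL atlas without the cerebellum and
#' without the pallidum (dropped for signal drop-out in basal structures).
#'
#' @return character vector of 88 region names.
#' @export
aal88_labels <- function() {
  path <- system.file("extdata", "aal88_labels.txt", package = "multisitefc")
  if (!nzchar(path)) stop("bundled label file not found; is the package installed?")
  readLines(path)
}
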