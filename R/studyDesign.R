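#' Construct a StudyDesign
#'
#' @param samples character vector of sample identifiers.
#' @param otu named character vector mapping each sample to its OTU label, or
#'   an unnamed vector parallel to `samples`.
#' @param phenotypes data.frame, one row per OTU (rownames = OTU labels), one
#'   column per feature; `NA` marks a feature that does not apply (polarity
#'   for biphasic OTUs).
#' @param features ordered feature names; defaults to the phenotype columns.
#' @return A [StudyDesign-class] object.
#' @export
StudyDesign <- function(samples, otu, phenotypes,
                        features = colnames(phenotypes)) {
  if (is.null(names(otu))) names(otu) <- samples
  phenotypes[] <- lapply(phenotypes, as.character)
  new("StudyDesign",
      samples = as.character(samples),
      otu = otu[samples],
      phenotypes = phenotypes,
      features = as.character(features))
}

#' The packaged 11-sample, five-OTU electric-organ study design
#'
#' Five *Paramormyrops* OTUs sampled from the wild: *P. kingsleyae* N-type
#' (3 samples; long EOD, biphasic), *P. kingsleyae* P-type (2; long,
#' triphasic, small penetrations), *P.* sp. 'magnostipes type I' (2; long,
#' triphasic, large penetrations), *P.* sp. 'magnostipes type II' (2; long,
#' triphasic, small penetrations) and *P.* sp. 'SN3' (2; short, biphasic).
#' Waveform polarity applies only to the triphasic OTUs.
#'
#' @return A [StudyDesign-class] with 11 samples over 5 OTUs.
#' @examples
#' d <- makePaperDesign()
#' table(otuOf(d, sampleIds(d)))
#' @export
makePaperDesign <- function() {
  samples <- c("PKINGN_6898", "PKINGN_6900", "PKINGN_6901",
               "PKINGP_6716", "PKINGP_6718",
               "PMAG1_6780", "PMAG1_6787",
               "PMAG2_6768", "PMAG2_6769",
               "PSN3_6739", "PSN3_6742")
  otu <- setNames(sub("_.*$", "", samples), samples)
  phen <- data.frame(
    duration   = c("long", "long", "long", "long", "short"),
    complexity = c("biphasic", "triphasic", "triphasic", "triphasic", "biphasic"),
    polarity   = c(NA, "small", "large", "small", NA),
    row.names  = c("PKINGN", "PKINGP", "PMAG1", "PMAG2", "PSN3"),
    stringsAsFactors = FALSE
  )
  StudyDesign(samples, otu, phen)
}

#' Default between-OTU phylogenetic distances
#'
#' Relative distances consistent with published *Paramormyrops* phylogenies:
#' conspecific morphs (*P. kingsleyae* N/P; 'magnostipes' I/II) are closest,
#' the 'magnostipes' pair and *P. kingsleyae* are intermediate, and
#' *P.* sp. 'SN3' is the most distant from all others.  Units are arbitrary;
#' only the ranking matters for selecting informative comparisons.
#'
#' @return Symmetric 5x5 numeric matrix over the packaged OTU labels.
#' @export
defaultOtuDistances <- function() {
  o <- c("PKINGN", "PKINGP", "PMAG1", "PMAG2", "PSN3")
  m <- matrix(0, 5, 5, dimnames = list(o, o))
  set <- function(a, b, d) {
    m[a, b] <<- d
    m[b, a] <<- d
  }
  set("PKINGN", "PKINGP", 1)
  set("PMAG1", "PMAG2", 1)
  set("PKINGN", "PMAG1", 2.5); set("PKINGN", "PMAG2", 2.5)
  set("PKINGP", "PMAG1", 2);   set("PKINGP", "PMAG2", 2)
  set("PKINGN", "PSN3", 3);    set("PKINGP", "PSN3", 3)
  set("PMAG1", "PSN3", 3);     set("PMAG2", "PSN3", 3)
  m
}

#' @name StudyDesign-accessors
#' @title Accessors for StudyDesign
#' @param x a [StudyDesign-class].
#' @param samples sample identifiers.
#' @param otu an OTU label.
#' @param feature a feature name (`"duration"`, `"complexity"`, `"polarity"`).
NULL

#' @rdname StudyDesign-accessors
#' @export
setMethod("sampleIds", "StudyDesign", function(x) x@samples)

#' @rdname StudyDesign-accessors
#' @export
setMethod("otuOf", "StudyDesign", function(x, samples) unname(x@otu[samples]))

#' @rdname StudyDesign-accessors
#' @export
setMethod("otuLabels", "StudyDesign", function(x) rownames(x@phenotypes))

#' @rdname StudyDesign-accessors
#' @export
setMethod("eodFeatures", "StudyDesign", function(x) x@features)

#' @rdname StudyDesign-accessors
#' @export
setMethod("phenotypeOf", "StudyDesign", function(x, otu, feature) {
  stopifnot(feature %in% x@features)
  x@phenotypes[otu, feature]
})

#' @rdname StudyDesign-accessors
#' @export
setMethod("samplesOfOtu", "StudyDesign", function(x, otu)
  x@samples[x@otu[x@samples] %in% otu])

#' Samples grouped by phenotype for one feature
#'
#' Samples from OTUs for which the feature is not applicable (polarity in
#' biphasic OTUs) are omitted.
#'
#' @rdname StudyDesign-accessors
#' @return `phenotypeGroups`: named list phenotype -> sample identifiers.
#' @export
setMethod("phenotypeGroups", "StudyDesign", function(x, feature) {
  ph <- phenotypeOf(x, otuOf(x, x@samples), feature)
  keep <- !is.na(ph)
  split(x@samples[keep], ph[keep])
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@samples), "samples,",
      nrow(object@phenotypes), "OTUs\n")
  cat("features:", paste(object@features, collapse = ", "), "\n")
  tab <- table(object@otu)
  cat("samples per OTU:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' Write / read a StudyDesign as two TSV files
#'
#' `samples.tsv` has columns `sample`, `otu`; `phenotypes.tsv` has `otu`
#' followed by one column per feature (empty string = not applicable).
#'
#' @param design a [StudyDesign-class].
#' @param dir directory to write into (created if needed).
#' @return `writeStudyDesign` the directory, invisibly; `readStudyDesign`
#'   a [StudyDesign-class].
#' @export
writeStudyDesign <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(sample = design@samples, otu = unname(design@otu[design@samples])),
    file.path(dir, "samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- cbind(otu = rownames(design@phenotypes), design@phenotypes)
  ph[is.na(ph)] <- ""
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeStudyDesign
#' @export
readStudyDesign <- function(dir) {
  smp <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  ph <- utils::read.table(file.path(dir, "phenotypes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  rownames(ph) <- ph$otu
  ph$otu <- NULL
  StudyDesign(smp$sample, setNames(smp$otu, smp$sample), ph)
}
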