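#' Published genome feature table (36 plant genome samples)
#'
#' Genome size (Mb), Helitron 3'-terminus count and Helitron density
#' (Helitrons per Mb) for 34 published genome assemblies spanning seven
#' species groups (rice japonica and indica, Arabidopsis thaliana
#' ecotypes, two Thellungiella groups, Brassica oleracea, maize), plus two
#' de novo A. thaliana draft assemblies used as classification test
#' samples (`role == "test"`). This is the worked training/test set for
#' [lda_classify()].
#'
#' @return Data frame: `group`, `genome`, `genome_size`, `helitron_count`,
#'   `density`, `role`.
#' @export
genome_feature_table <- function() {
  read.delim(system.file("extdata", "genome_features.tsv",
                         package = "helscan"), stringsAsFactors = FALSE)
}

#' A. thaliana ecotype table (18 ecotypes)
#'
#' Genome size, Helitron count, density and flowering-time class for 18
#' A. thaliana ecotypes; the phenotype margins (5 late, 13 intermediate)
#' drive the association-rule examples.
#'
#' @return Data frame: `accession`, `country`, `genome_size`,
#'   `helitron_count`, `density`, `flowering_time`.
#' @export
ath_ecotype_table <- function() {
  read.delim(system.file("extdata", "ath_ecotypes.tsv",
                         package = "helscan"), stringsAsFactors = FALSE)
}
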