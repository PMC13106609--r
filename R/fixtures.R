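#' Packaged reference tables from the 48-accession oat screen
#'
#' Two published summary tables ship with the package as plain-text
#' fixtures so late pipeline stages can be exercised without raw data:
#' `"table2"`, per-trait descriptive statistics (range, mean, SD, CV) under
#' control and high-light stress, and `"table3"`, the 48 genotypes'
#' comprehensive evaluation index (CI) values with their published ranks.
#'
#' @param name `"table2"` or `"table3"`.
#' @return data.frame; `table2` has one row per trait x treatment,
#'   `table3` one row per genotype (code, genotype, ci, rank).
#' @export
load_fixture <- function(name = c("table2", "table3")) {
  name <- match.arg(name)
  file <- switch(name,
                 table2 = "table2_descriptive_stats.csv",
                 table3 = "table3_ci.csv")
  path <- system.file("extdata", file, package = "heliotol")
  if (path == "") stop("fixture not found: ", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
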