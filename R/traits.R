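#' Canonical trait names
#'
#' The nine seedling traits scored in a high-light screen, in their canonical
#' column tokens: plant height (cm), stem diameter (mm), SPAD chlorophyll
#' index, leaf thickness (mm), aboveground fresh weight (g), aboveground dry
#' weight (g), net photosynthetic rate (umol m-2 s-1), free proline (ug/g)
#' and Rubisco activity (nmol/min/g).
#'
#' @return Character vector of the nine canonical trait tokens.
#' @export
hl_traits <- function() {
  c("plant_height", "stem_diameter", "spad", "leaf_thickness",
    "afw", "adw", "pn", "proline", "rubisco")
}

.treatments <- c("control", "stress")

#' Construct a validated replicate-level trait table
#'
#' A trait table is the single ingestion point of the evaluation pipeline:
#' long-format records of genotype x treatment x replicate x trait
#' measurements. Treatment and trait tokens are normalised to lower case and
#' validated against the canonical sets; values must be finite and, for all
#' nine traits, non-negative.
#'
#' @param df data.frame with columns `genotype`, `treatment`, `replicate`,
#'   `trait`, `value`.
#' @return A `trait_table` (a data.frame with normalised, validated columns).
#' @export
trait_table <- function(df) {
  need <- c("genotype", "treatment", "replicate", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  df$genotype <- as.character(df$genotype)
  df$treatment <- tolower(trimws(as.character(df$treatment)))
  bad_trt <- setdiff(unique(df$treatment), .treatments)
  if (length(bad_trt) > 0L) {
    stop("unknown treatment level(s): ", paste(bad_trt, collapse = ", "))
  }
  df$trait <- tolower(trimws(as.character(df$trait)))
  bad_trait <- setdiff(unique(df$trait), hl_traits())
  if (length(bad_trait) > 0L) {
    stop("unknown trait name(s): ", paste(bad_trait, collapse = ", "))
  }
  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    if (anyNA(v) & !anyNA(df$value)) {
      stop("non-numeric value at row ", which(is.na(v))[1L])
    }
    df$value <- v
  }
  if (any(!is.finite(df$value))) {
    stop("non-finite trait value at row ", which(!is.finite(df$value))[1L])
  }
  if (any(df$value < 0)) {
    stop("negative trait value at row ", which(df$value < 0)[1L])
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop("replicate indices must be positive integers")
  }
  key <- paste(df$genotype, df$treatment, df$trait, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate replicate index within (genotype, treatment, trait): row ",
         which(duplicated(key))[1L])
  }
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a replicate-level trait table from CSV
#'
#' @param path CSV file with header. Default column names are
#'   `genotype,treatment,replicate,trait,value`; `schema` remaps them.
#' @param schema optional named character vector mapping the canonical column
#'   names to the names used in the file, e.g.
#'   `c(genotype = "accession", value = "measurement")`.
#' @return A validated [trait_table()].
#' @export
read_trait_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c(genotype = "genotype", treatment = "treatment",
            replicate = "replicate", trait = "trait", value = "value")
  if (!is.null(schema)) cols[names(schema)] <- unname(schema)
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss) > 0L) {
    stop("input is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- raw[, unname(cols)]
  names(df) <- names(cols)
  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    if (anyNA(v)) {
      stop("non-numeric value at data row ", which(is.na(v))[1L],
           " of ", basename(path))
    }
    df$value <- v
  }
  trait_table(df)
}

#' Write a trait table to CSV
#'
#' @param table a [trait_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicates within genotype x treatment x trait
#'
#' Replicate means are the unit of every downstream stage: tolerance
#' coefficients, descriptive statistics, associations and the path model all
#' consume genotype-level means, never raw replicates.
#'
#' @param table a [trait_table()].
#' @return A `genotype_means` data.frame with columns `genotype`, `treatment`,
#'   `trait`, `mean`, `n_replicates`.
#' @export
aggregate_replicates <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  agg <- stats::aggregate(value ~ genotype + treatment + trait,
                          data = as.data.frame(table), FUN = mean)
  cnt <- stats::aggregate(value ~ genotype + treatment + trait,
                          data = as.data.frame(table), FUN = length)
  out <- data.frame(genotype = agg$genotype, treatment = agg$treatment,
                    trait = agg$trait, mean = agg$value,
                    n_replicates = as.integer(cnt$value),
                    stringsAsFactors = FALSE)
  out <- out[order(out$genotype, out$treatment, out$trait), ]
  rownames(out) <- NULL
  class(out) <- c("genotype_means", "data.frame")
  out
}

#' Per-trait descriptive statistics over genotype means
#'
#' Statistics describe inter-genotype variation: each trait is first averaged
#' over replicates within genotype, then min/max/mean/SD/CV are taken over the
#' genotype means within one treatment. SD is the sample (n-1) standard
#' deviation; the coefficient of variation is `100 * sd / mean`.
#'
#' @param table a [trait_table()].
#' @param treatment `"control"` or `"stress"`.
#' @return data.frame with one row per trait: `trait`, `treatment`, `min`,
#'   `max`, `mean`, `sd`, `cv_percent`. Traits with zero mean get `NA` CV and
#'   a warning (CV undefined).
#' @export
descriptive_stats <- function(table, treatment = c("control", "stress")) {
  treatment <- match.arg(treatment)
  means <- aggregate_replicates(table)
  means <- means[means$treatment == treatment, ]
  traits <- intersect(hl_traits(), unique(means$trait))
  rows <- lapply(traits, function(tr) {
    v <- means$mean[means$trait == tr]
    if (length(v) < 2L) {
      stop("descriptive_stats needs >= 2 genotype means for trait ", tr)
    }
    m <- mean(v)
    s <- stats::sd(v)
    cv <- if (m == 0) NA_real_ else cv_percent(m, s)
    data.frame(trait = tr, treatment = treatment,
               min = min(v), max = max(v), mean = m, sd = s,
               cv_percent = cv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$cv_percent)) {
    warning("CV undefined (zero mean) for: ",
            paste(out$trait[is.na(out$cv_percent)], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Coefficient of variation in percent
#'
#' @param mean,sd trait mean and standard deviation (same units).
#' @return `100 * sd / mean`.
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop("CV undefined for zero mean")
  100 * sd / mean
}

#' Signed percent change from control to stress
#'
#' @param control_mean,stress_mean trait means under the two treatments.
#' @return `100 * (stress_mean - control_mean) / control_mean`; negative for
#'   a decline under stress.
#' @export
percent_change <- function(control_mean, stress_mean) {
  if (any(control_mean == 0)) stop("percent change undefined: control mean is 0")
  100 * (stress_mean - control_mean) / control_mean
}
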