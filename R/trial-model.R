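#' @keywords internal
"_PACKAGE"

# Column schema for trial CSVs; one scored vial per row.
TRIAL_COLUMNS <- c("site", "pair_id", "ph_treatment", "ph_measured",
                   "vial_index", "sperm_conc",
                   "n_scored", "n_unfert", "n_tight", "n_abn_dev")

SITE_LABELS <- c("FC", "BMR", "SB")
TREATMENT_LABELS <- c("8.03", "7.87", "7.76", "7.61")

#' Construct and validate vial scoring counts
#'
#' A scored vial records, out of `n_scored` embryos examined, how many showed
#' no fertilization membrane (`n_unfert`), a tight fertilization membrane
#' (`n_tight`), or a normal envelope with unequal cleavage (`n_abn_dev`).
#' The remainder are normally fertilized.
#'
#' @param n_scored total embryos scored (typically 200).
#' @param n_unfert embryos with no fertilization membrane.
#' @param n_tight embryos with a tight fertilization membrane.
#' @param n_abn_dev embryos with a normal envelope but abnormal cleavage.
#' @return A `vial_counts` object (named list) with the derived `n_normal`.
#' @export
vial_counts <- function(n_scored, n_unfert, n_tight, n_abn_dev) {
  counts <- c(n_scored = n_scored, n_unfert = n_unfert,
              n_tight = n_tight, n_abn_dev = n_abn_dev)
  if (any(!is.finite(counts)) || any(counts != round(counts)))
    stop("vial counts must be finite integers")
  if (any(counts < 0))
    stop("vial counts must be non-negative: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  n_normal <- n_scored - n_unfert - n_tight - n_abn_dev
  if (n_normal < 0)
    stop("count partition violated: n_unfert + n_tight + n_abn_dev exceeds n_scored")
  structure(list(n_scored = n_scored, n_unfert = n_unfert, n_tight = n_tight,
                 n_abn_dev = n_abn_dev, n_normal = n_normal),
            class = "vial_counts")
}

#' Score a vial into fertilization proportions
#'
#' Computes the three standard scoring proportions: total fertilization
#' TF = (scored - unfertilized) / scored; abnormal fertilization
#' AbnF = (tight membrane + abnormal cleavage) / fertilized, defined only when
#' at least one egg was fertilized; and normal fertilization
#' NF = TF * (1 - AbnF), taken as 0 when TF = 0.
#'
#' @param counts a [vial_counts()] object.
#' @return list with `tf`, `abnf`, `nf` and `abnf_defined`. When TF = 0,
#'   `abnf` is `NA` and `abnf_defined` is `FALSE`.
#' @export
score_vial <- function(counts) {
  if (!inherits(counts, "vial_counts"))
    counts <- do.call(vial_counts, as.list(counts)[c("n_scored", "n_unfert",
                                                     "n_tight", "n_abn_dev")])
  if (counts$n_scored <= 0) stop("n_scored must be positive")
  n_fert <- counts$n_scored - counts$n_unfert
  tf <- n_fert / counts$n_scored
  if (n_fert == 0) {
    list(tf = 0, abnf = NA_real_, nf = 0, abnf_defined = FALSE)
  } else {
    abnf <- (counts$n_tight + counts$n_abn_dev) / n_fert
    list(tf = tf, abnf = abnf, nf = tf * (1 - abnf), abnf_defined = TRUE)
  }
}

#' Score every vial of a trial table
#'
#' @param records data frame in the trial CSV schema (see [load_trials()]).
#' @return `records` with columns `tf`, `abnf`, `nf`, `abnf_defined` appended.
#' @export
score_trials <- function(records) {
  validate_trials(records)
  scored <- lapply(seq_len(nrow(records)), function(i)
    score_vial(vial_counts(records$n_scored[i], records$n_unfert[i],
                           records$n_tight[i], records$n_abn_dev[i])))
  records$tf <- vapply(scored, `[[`, numeric(1), "tf")
  records$abnf <- vapply(scored, `[[`, numeric(1), "abnf")
  records$nf <- vapply(scored, `[[`, numeric(1), "nf")
  records$abnf_defined <- vapply(scored, `[[`, logical(1), "abnf_defined")
  records
}

#' Serial-dilution sperm concentrations
#'
#' Computes the sperm concentration in each vial of a 1:10 serial dilution
#' series.  The stock concentration is taken from a hemocytometer count of the
#' (pre-diluted) stock; each transfer adds `step_volume_ratio` of the previous
#' vial into treatment water (2.3 ml into 20.7 ml in the bench protocol, i.e.
#' exactly 1:10).
#'
#' @param hemocytometer_count sperm per microlitre counted in the stock.
#' @param n_steps number of serial vials (default 8).
#' @param step_volume_ratio volume fraction transferred per step
#'   (default 2.3/23, equal to `1/step_factor`).
#' @param step_factor nominal dilution factor per step (default 10).
#' @param predilution_factor dilution already applied to the concentrated
#'   sperm before the stock count (default 100; recorded for provenance, the
#'   hemocytometer count already refers to the stock so it does not rescale).
#' @return numeric vector of length `n_steps`, strictly decreasing; vial k
#'   holds `stock * step_volume_ratio^k`.
#' @export
dilution_concentrations <- function(hemocytometer_count, n_steps = 8,
                                    step_volume_ratio = 2.3 / 23,
                                    step_factor = 10,
                                    predilution_factor = 100) {
  if (!is.finite(hemocytometer_count) || hemocytometer_count <= 0)
    stop("hemocytometer_count must be positive")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (step_factor <= 1 || predilution_factor < 1)
    stop("dilution factors must exceed 1")
  if (step_volume_ratio <= 0 || step_volume_ratio >= 1)
    stop("step_volume_ratio must be in (0, 1)")
  hemocytometer_count * step_volume_ratio ^ seq_len(n_steps)
}

# Analysis windows (open intervals on sperm/ul) within which the response is
# not uniformly 0 or 100%.
ANALYSIS_WINDOWS <- list(tf = c(1, 2e5), abnf = c(1e2, 2e7))

#' Restrict trial records to a response's analysis window
#'
#' The cubic logit models are fitted only where the response is informative:
#' sperm concentrations strictly inside (1, 2e5) per microlitre for TF and
#' strictly inside (1e2, 2e7) for AbnF.
#'
#' @param records trial data frame with a `sperm_conc` column.
#' @param response `"tf"` or `"abnf"`.
#' @param window optional numeric length-2 override of the open interval.
#' @return the retained rows of `records`.
#' @export
filter_analysis_window <- function(records, response = c("tf", "abnf"),
                                   window = NULL) {
  response <- match.arg(response)
  if (is.null(window)) window <- ANALYSIS_WINDOWS[[response]]
  stopifnot(length(window) == 2, window[1] < window[2])
  records[records$sperm_conc > window[1] & records$sperm_conc < window[2], ,
          drop = FALSE]
}

validate_trials <- function(records) {
  missing <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  counts <- records[c("n_scored", "n_unfert", "n_tight", "n_abn_dev")]
  bad <- which(Reduce(`|`, lapply(counts, function(x) !is.finite(x) | x < 0)))
  if (length(bad))
    stop("negative or non-finite counts in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  over <- which(records$n_unfert + records$n_tight + records$n_abn_dev >
                  records$n_scored)
  if (length(over))
    stop("counts exceed n_scored in row(s): ",
         paste(utils::head(over, 5), collapse = ", "))
  bad_site <- which(!records$site %in% SITE_LABELS)
  if (length(bad_site))
    stop("unknown site label in row(s): ",
         paste(utils::head(bad_site, 5), collapse = ", "))
  bad_trt <- which(!as.character(records$ph_treatment) %in% TREATMENT_LABELS)
  if (length(bad_trt))
    stop("unknown pH treatment label in row(s): ",
         paste(utils::head(bad_trt, 5), collapse = ", "))
  if (any(records$sperm_conc <= 0))
    stop("sperm_conc must be positive")
  invisible(records)
}

#' Read or write fertilization-trial tables
#'
#' The trial CSV has one scored vial per row and columns
#' `site,pair_id,ph_treatment,ph_measured,vial_index,sperm_conc,n_scored,`
#' `n_unfert,n_tight,n_abn_dev`.  Validation failures name the offending
#' column or rows.
#'
#' @param path CSV file path.
#' @return `load_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
load_trials <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(ph_treatment = "character"))
  records$ph_treatment <- as.character(records$ph_treatment)
  validate_trials(records)
  records
}

#' @rdname load_trials
#' @param records trial data frame to write.
#' @export
write_trials <- function(records, path) {
  validate_trials(records)
  utils::write.csv(records[union(TRIAL_COLUMNS,
                                 names(records))], path, row.names = FALSE)
  invisible(path)
}
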