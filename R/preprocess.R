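# Feature encoding and standardization ahead of clustering, plus the bowel
# preparation adequacy rule.

# Variables encoded as presence indicators (presence = 1) rather than by
# alphabetical label order.
presence_encodings <- list(
  environment = c(urban = 0L, rural = 1L),  # rural residence is the exposure
  sex = c(female = 0L, male = 1L)
)

#' Label-encode a participant table into a numeric matrix
#'
#' Binary variables become \{0, 1\} indicators: residence encodes rural as 1
#' (presence of the disadvantage factor), sex encodes male as 1; antiplatelet,
#' anticoagulant and malignant are already 0/1. Education is kept as its
#' ISCED 0-8 ordinal. Remaining categoricals (comorbidity category, diagnosis)
#' are label-encoded with an alphabetical label-to-integer map for
#' determinism. Continuous variables pass through unchanged; standardize
#' separately with \code{\link{standardize}}.
#'
#' @param table Non-empty participant data frame.
#' @param columns Variables to encode, in output order. Defaults to the
#'   clustering feature set: age, FIT value, sex, residence, education,
#'   comorbidity category and count, medications, diagnosis and malignancy
#'   (columns absent from \code{table} are skipped).
#' @param scheme Optional \code{encoding_scheme} from a previous call; when
#'   supplied its maps are reused and unseen labels raise an error naming the
#'   variable and label.
#' @return List with \code{matrix} (numeric, one column per encoded variable)
#'   and \code{scheme} (class \code{encoding_scheme}: the label maps and the
#'   set of continuous columns).
#' @export
encode_features <- function(table,
                            columns = c("age", "fit_value", "sex",
                                        "environment", "education",
                                        "comorbidity_category",
                                        "comorbidity_count", "antiplatelet",
                                        "anticoagulant", "diagnosis",
                                        "malignant"),
                            scheme = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("'table' must be a non-empty data frame")
  columns <- intersect(columns, names(table))
  if (length(columns) == 0) stop("no requested columns present in 'table'")
  maps <- if (is.null(scheme)) list() else scheme$categorical_maps
  out <- matrix(NA_real_, nrow(table), length(columns),
                dimnames = list(NULL, columns))
  continuous <- character(0)
  for (v in columns) {
    x <- table[[v]]
    if (is.numeric(x) || is.logical(x)) {
      out[, v] <- as.numeric(x)
      if (!v %in% c("education", "antiplatelet", "anticoagulant",
                    "malignant", "completed_colonoscopy"))
        continuous <- c(continuous, v)
      next
    }
    x <- as.character(x)
    if (is.null(maps[[v]])) {
      maps[[v]] <- if (v %in% names(presence_encodings)) presence_encodings[[v]]
      else {
        labs <- sort(unique(x[!is.na(x)]))  # alphabetical for determinism
        stats::setNames(seq_along(labs) - 1L, labs)
      }
    }
    unseen <- setdiff(unique(x[!is.na(x)]), names(maps[[v]]))
    if (length(unseen))
      stop("unseen label for variable '", v, "': ",
           paste(unseen, collapse = ", "))
    out[, v] <- as.numeric(maps[[v]][x])
  }
  scheme <- structure(list(categorical_maps = maps,
                           continuous = continuous,
                           continuous_stats = if (is.null(scheme)) NULL
                                              else scheme$continuous_stats),
                      class = "encoding_scheme")
  list(matrix = out, scheme = scheme)
}

#' Decode an encoded column back to labels
#'
#' Inverse of the label map stored in an \code{encoding_scheme}; used to
#' verify that encoding round-trips every categorical label.
#'
#' @param codes Integer codes.
#' @param variable Variable name.
#' @param scheme An \code{encoding_scheme}.
#' @return Character labels.
#' @export
decode_feature <- function(codes, variable, scheme) {
  map <- scheme$categorical_maps[[variable]]
  if (is.null(map)) stop("no map stored for variable '", variable, "'")
  names(map)[match(codes, map)]
}

#' Z-score standardization
#'
#' Standardizes the given columns to mean 0, sd 1 using the population
#' (\code{n}) denominator. When \code{scheme} already carries fitted
#' statistics they are applied unchanged (inference-time transform);
#' otherwise statistics are fitted on \code{matrix} and stored.
#'
#' @param matrix Numeric matrix from \code{\link{encode_features}}.
#' @param scheme An \code{encoding_scheme}; its \code{continuous} element
#'   names the columns to standardize.
#' @param columns Columns to standardize; defaults to
#'   \code{scheme$continuous}, or every column when no scheme is given.
#' @return List with the standardized \code{matrix} and the updated
#'   \code{scheme} (fitted means/sds in \code{continuous_stats}).
#' @export
standardize <- function(matrix, scheme = NULL, columns = NULL) {
  if (is.null(columns))
    columns <- if (!is.null(scheme)) scheme$continuous else colnames(matrix)
  columns <- intersect(columns, colnames(matrix))
  stats_tab <- if (!is.null(scheme)) scheme$continuous_stats else NULL
  if (is.null(stats_tab)) {
    n <- nrow(matrix)
    mu <- colMeans(matrix[, columns, drop = FALSE])
    sdev <- sqrt(colMeans(sweep(matrix[, columns, drop = FALSE], 2, mu)^2))
    if (any(sdev <= 0))
      stop("zero-variance column(s): ",
           paste(columns[sdev <= 0], collapse = ", "))
    stats_tab <- data.frame(column = columns, mean = mu, sd = sdev,
                            row.names = NULL)
  }
  for (i in seq_len(nrow(stats_tab))) {
    v <- stats_tab$column[i]
    if (v %in% colnames(matrix))
      matrix[, v] <- (matrix[, v] - stats_tab$mean[i]) / stats_tab$sd[i]
  }
  if (is.null(scheme))
    scheme <- structure(list(categorical_maps = list(), continuous = columns),
                        class = "encoding_scheme")
  scheme$continuous_stats <- stats_tab
  list(matrix = matrix, scheme = scheme)
}

#' Bowel preparation adequacy (Boston scale)
#'
#' A colonoscopy is adequately prepared when the total Boston Bowel
#' Preparation Scale score over the right, transverse and left colon is at
#' least 6 and every segment scores at least 2.
#'
#' @param right,transverse,left Integer segment scores in 0-3 (vectorized).
#' @return Logical vector.
#' @examples
#' bbps_adequate(2, 2, 2)   # TRUE
#' bbps_adequate(3, 3, 0)   # FALSE: one segment below 2
#' @export
bbps_adequate <- function(right, transverse, left) {
  s <- cbind(right, transverse, left)
  if (any(is.na(s)) || any(s < 0 | s > 3) || any(s != floor(s)))
    stop("BBPS segment scores must be integers in 0-3")
  rowSums(s) >= 6 & apply(s, 1, min) >= 2
}

#' Clustering feature matrix for a participant table
#'
#' Builds the standardized numeric matrix fed to the autoencoder: age, FIT
#' value, sex, residence, ISCED education, comorbidity category and count and
#' antithrombotic indicators, plus indicator (one-hot) columns for the benign
#' colonoscopy diagnoses. The carcinoma and malignant-polyp indicators and
#' the malignancy flag are collinear encodings of the outcome; at most one
#' side enters the matrix, controlled by the two switches.
#'
#' @param table Participant data frame.
#' @param include_diagnosis Add benign-diagnosis indicator columns
#'   (default TRUE).
#' @param include_malignant Add the malignant-lesion flag instead
#'   (default FALSE); enabling both is refused.
#' @return Standardized numeric matrix (population z-scores, all columns).
#' @export
clustering_features <- function(table, include_diagnosis = TRUE,
                                include_malignant = FALSE) {
  if (include_diagnosis && include_malignant)
    stop("diagnosis indicators and the malignancy flag are collinear; enable at most one")
  base <- c("age", "fit_value", "sex", "environment", "education",
            "comorbidity_category", "comorbidity_count", "antiplatelet",
            "anticoagulant")
  enc <- encode_features(table, columns = base)
  m <- enc$matrix
  if (include_diagnosis) {
    benign <- setdiff(diagnosis_categories(), malignant_diagnoses())
    oh <- vapply(benign, function(d) as.numeric(table$diagnosis == d),
                 numeric(nrow(table)))
    m <- cbind(m, oh)
  }
  if (include_malignant) m <- cbind(m, malignant = table$malignant)
  standardize(m, columns = colnames(m))$matrix
}
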