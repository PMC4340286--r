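# Internal helpers shared across the package.

# Axis labels, fixed order: anterior-posterior, superior-inferior, left-right.
AXES <- c("ap", "si", "lr")

# Shift-log column names (all displacements stored in cm).
SHIFT_COLS <- c("ap_cm", "si_cm", "lr_cm")

#' @noRd
stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "setupmargins_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_insufficient <- function(msg, ...) stop_with("insufficient_data_error", msg, ...)
stop_validation <- function(msg, ...) stop_with("validation_error", msg, ...)
stop_schema <- function(msg, ...) stop_with("schema_error", msg, ...)
stop_domain <- function(msg, ...) stop_with("domain_error", msg, ...)

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used in the clinical tables this package reproduces), unlike base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_away(0.865, 2)  # 0.87
#' round_away(-0.005, 2) # -0.01
#' @export
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Check a numeric scalar/vector argument.
check_numeric <- function(x, name, finite = TRUE, min = NULL) {
  if (!is.numeric(x)) stop_validation("`%s` must be numeric", name)
  if (finite && any(!is.finite(x))) stop_validation("`%s` must be finite", name)
  if (!is.null(min) && any(x < min, na.rm = TRUE)) {
    stop_validation("`%s` must be >= %s", name, format(min))
  }
  invisible(x)
}

# Sample SD that returns NA (not an error) for n < 2.
sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}
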