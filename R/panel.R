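#' Default common time grid over one circadian cycle
#'
#' `n` equally spaced points covering `[0, 24)` h. The default `n = 96`
#' (15-min step) keeps the forward-difference ODE inversion of the
#' residual-trajectory module numerically faithful; coarser grids distort
#' the recovered forcing.
#'
#' @param n Number of grid points.
#' @return Numeric vector of times (h).
#' @export
common_grid <- function(n = 96) seq(0, 24, length.out = n + 1)[seq_len(n)]

#' Canonical regulator ordering
#'
#' Feature columns of a regulator panel: the five systemic biomarkers
#' followed by their integral (indirect-action) transforms. Feature `j + 5`
#' is always the integral of feature `j`.
#'
#' @return Character vector of 10 feature names.
#' @export
regulator_features <- function() {
  direct <- c("activity", "temperature", "food_intake",
              "corticosterone", "melatonin")
  c(direct, paste0("int_", direct))
}

#' Integral regulator transform
#'
#' Cumulative trapezoidal integral of the mean-centered signal, zero at the
#' first grid point. Centering keeps the integral of a periodic signal
#' periodic (the raw integral of a positive biomarker is an unbounded ramp);
#' the removed constant is absorbed by standardization downstream. Set
#' `center = FALSE` for the literal running integral.
#'
#' @param values Signal on the grid.
#' @param grid Strictly increasing times (h).
#' @param center Subtract the mean before integrating (default TRUE).
#' @return Numeric vector, same length as `values`, first element 0.
#' @export
#' @examples
#' g <- seq(0, 24, by = 0.1)
#' z <- cos(2 * pi * g / 24)
#' max(abs(integral_regulator(z, g) - 24 / (2 * pi) * sin(2 * pi * g / 24)))
integral_regulator <- function(values, grid, center = TRUE) {
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  x <- if (center) {
    # trapezoidal mean, so the centered integral closes over the span
    values - pracma::trapz(grid, values) / diff(range(grid))
  } else {
    values
  }
  drop(pracma::cumtrapz(grid, x))
}

# population (1/n) standard deviation: makes the empty-model loss on a
# standardized trajectory exactly 1
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

standardize_vec <- function(x) {
  m <- mean(x); s <- sd_pop(x)
  if (s == 0) stop("cannot standardize a constant vector")
  list(values = (x - m) / s, mean = m, sd = s)
}

#' Build the 10-column regulator panel for one class
#'
#' Assembles the five smoothed biomarkers and their integral regulators on
#' the common grid and standardizes every column to zero mean and unit
#' (population) standard deviation, keeping the standardization record for
#' inverse transforms.
#'
#' @param smooth_list Named list of five `smooth_series` (names must be the
#'   direct features of [regulator_features()]), all on the same grid.
#' @param class_id Integer 1-4.
#' @return A `regulator_panel`: list with `grid`, `z` (N x 10 standardized
#'   matrix), `scale` (data.frame feature/mean/sd), `class_id`.
#' @export
build_panel <- function(smooth_list, class_id = NA_integer_) {
  direct <- regulator_features()[1:5]
  if (!all(direct %in% names(smooth_list))) {
    stop("smooth_list must contain: ", paste(direct, collapse = ", "))
  }
  grid <- smooth_list[[direct[1]]]$grid
  for (b in direct) {
    if (!isTRUE(all.equal(smooth_list[[b]]$grid, grid))) {
      stop("mismatched grids: ", b)
    }
  }
  raw <- sapply(direct, function(b) smooth_list[[b]]$mean)
  ints <- sapply(direct, function(b) integral_regulator(raw[, b], grid))
  mat <- cbind(raw, ints)
  colnames(mat) <- regulator_features()
  recs <- apply(mat, 2, standardize_vec, simplify = FALSE)
  z <- sapply(recs, `[[`, "values")
  colnames(z) <- regulator_features()
  scale <- data.frame(feature = regulator_features(),
                      mean = vapply(recs, `[[`, numeric(1), "mean"),
                      sd = vapply(recs, `[[`, numeric(1), "sd"),
                      row.names = NULL)
  structure(list(grid = grid, z = z, scale = scale, class_id = class_id),
            class = "regulator_panel")
}

#' @export
print.regulator_panel <- function(x, ...) {
  cat("<regulator_panel> class", x$class_id, ":", nrow(x$z), "x", ncol(x$z),
      "standardized features\n")
  invisible(x)
}

#' Undo panel standardization
#'
#' @param panel A `regulator_panel`.
#' @param feature Feature name.
#' @return The column on its original scale.
#' @export
unstandardize <- function(panel, feature) {
  r <- panel$scale[panel$scale$feature == feature, ]
  if (nrow(r) != 1) stop("unknown feature: ", feature)
  panel$z[, feature] * r$sd + r$mean
}

#' Serialize / load a regulator panel
#'
#' The matrix goes to CSV; the standardization record and grid to a JSON
#' sidecar with the same stem.
#'
#' @param panel A `regulator_panel`.
#' @param path CSV file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` a panel.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(cbind(time_h = panel$grid, as.data.frame(panel$z)),
                   path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(class_id = panel$class_id, scale = panel$scale),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  structure(list(grid = d$time_h,
                 z = as.matrix(d[, regulator_features()]),
                 scale = side$scale, class_id = side$class_id),
            class = "regulator_panel")
}
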