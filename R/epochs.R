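#' Construct a sensor-epochs container
#'
#' Holds epoched MEG sensor data as a `trial x channel x time` array together
#' with the sampling rate, per-trial condition labels and the acquisition
#' geometry. This is the common currency of the MEG half of the pipeline.
#'
#' @param data Numeric array `trials x channels x time`.
#' @param rate Sampling rate in Hz.
#' @param labels Tibble with one row per trial: columns `trial`, `condition`
#'   (`"rest"` or contrast percent as character), `contrast` (fraction, `NA`
#'   for rest) and `block`.
#' @param array A [meg_sensor_array()].
#' @param head A [head_model()].
#' @param eye `"left"` or `"right"`.
#' @return Object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(data, rate, labels, array, head,
                          eye = c("left", "right")) {
  eye <- match.arg(eye)
  stopifnot(length(dim(data)) == 3L, nrow(labels) == dim(data)[1],
            dim(data)[2] == nrow(array$positions), rate > 0)
  structure(list(data = data, rate = rate, labels = labels,
                 array = array, head = head, eye = eye),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sensor_epochs> %d trials x %d channels x %d samples @ %g Hz (%s eye)\n",
    d[1], d[2], d[3], x$rate, x$eye))
  print(table(x$labels$condition))
  invisible(x)
}

#' Subset the trials of a sensor-epochs container
#'
#' @param epochs A [sensor_epochs()] object.
#' @param which Logical or integer trial selector.
#' @return A `sensor_epochs` object with the selected trials.
#' @export
epochs_subset <- function(epochs, which) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  sensor_epochs(epochs$data[which, , , drop = FALSE], epochs$rate,
                epochs$labels[which, , drop = FALSE],
                epochs$array, epochs$head, epochs$eye)
}

stim_trials <- function(epochs) which(!is.na(epochs$labels$contrast))
rest_trials <- function(epochs) which(is.na(epochs$labels$contrast))
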