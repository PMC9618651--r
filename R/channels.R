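#' Channel naming scheme for the sensor sample matrix
#'
#' Input channels follow the `location_sensor_axis` convention for three
#' complementary-limb sensor locations (right ankle, right hip, chest), each
#' contributing ten quantities: triaxial accelerometer, triaxial gyroscope,
#' triaxial magnetometer and the accelerometer resultant (Euclidean norm).
#' The two targets are the left-ankle and left-hip resultant accelerations.
#'
#' @return A character vector of channel names.
#' @export
#' @examples
#' input_channel_names()
input_channel_names <- function() {
  locs <- c("rankle", "rhip", "chest")
  sensors <- c(
    "acc_x", "acc_y", "acc_z",
    "gyr_x", "gyr_y", "gyr_z",
    "mag_x", "mag_y", "mag_z",
    "acc_res"
  )
  as.vector(t(outer(locs, sensors, paste, sep = "_")))
}

#' @rdname input_channel_names
#' @export
target_channel_names <- function() {
  c("lankle_acc_res", "lhip_acc_res")
}

# Channels whose lagged combination defines the targets.
resultant_input_channels <- function() {
  c("rankle_acc_res", "rhip_acc_res", "chest_acc_res")
}

# Static (DC) level per input channel: gravity-dominated accelerometer
# resultants near 9.81 m/s^2, earth-field-scale magnetometer offsets,
# zero-mean angular rates.
channel_baselines <- function() {
  per_sensor <- c(
    acc_x = 0.4, acc_y = 0.3, acc_z = 9.2,
    gyr_x = 0, gyr_y = 0, gyr_z = 0,
    mag_x = 22, mag_y = -12, mag_z = 40,
    acc_res = 9.81
  )
  ch <- input_channel_names()
  out <- per_sensor[sub("^[a-z]+_", "", ch)]
  names(out) <- ch
  out
}

# Oscillation amplitude scale per sensor type (channel units).
channel_base_amplitudes <- function() {
  per_sensor <- c(
    acc_x = 1.6, acc_y = 1.4, acc_z = 1.8,
    gyr_x = 1.2, gyr_y = 1.0, gyr_z = 0.9,
    mag_x = 0.4, mag_y = 0.4, mag_z = 0.3,
    acc_res = 1.8
  )
  ch <- input_channel_names()
  out <- per_sensor[sub("^[a-z]+_", "", ch)]
  names(out) <- ch
  out
}

# Fixed linear combination defining each target from the three input
# resultant-acceleration channels (rows: targets, columns: inputs).
# Weights sum to one so a unit coupling gain keeps the targets on the
# gravity-dominated scale of the inputs.
coupling_weights <- function() {
  w <- rbind(
    lankle_acc_res = c(0.60, 0.25, 0.15),
    lhip_acc_res   = c(0.25, 0.55, 0.20)
  )
  colnames(w) <- resultant_input_channels()
  w
}
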