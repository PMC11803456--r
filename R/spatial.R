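# Relating attenuation status to cortical location: gyrus contingency and
# distance to the hand-knob reference point (MNI152 RAS millimetres).

#' Electrode table
#'
#' @param name Unique electrode names.
#' @param x,y,z MNI152 coordinates in mm (RAS convention).
#' @param region Region label: `"PreCG"`, `"PostCG"` or `"other"`.
#' @param ground Logical flag; ground electrodes are excluded from
#'   referencing and statistics.
#' @return Data frame of class `electrode_table`.
#' @export
electrode_table <- function(name, x, y, z, region,
                            ground = rep(FALSE, length(name))) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("electrode names must be unique", call. = FALSE)
  if (!all(is.finite(c(x, y, z))))
    stop("electrode coordinates must be finite", call. = FALSE)
  region <- as.character(region)
  bad <- setdiff(unique(region), c("PreCG", "PostCG", "other"))
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(data.frame(name = name, x = x, y = y, z = z, region = region,
                       ground = as.logical(ground)),
            class = c("electrode_table", "data.frame"))
}

#' @rdname electrode_table
#' @param path File path (tab-separated, header row).
#' @export
read_electrodes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "region", "ground")
  if (!all(need %in% names(df)))
    stop("electrode table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  electrode_table(df$name, df$x, df$y, df$z, df$region, df$ground)
}

#' @rdname electrode_table
#' @param electrodes An `electrode_table`.
#' @export
write_electrodes <- function(electrodes, path) {
  utils::write.table(as.data.frame(electrodes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gyrus-by-attenuation contingency
#'
#' Builds the 2x2 table of region (PreCG / PostCG) against attenuation
#' status over the supplied (significant) electrodes and applies Fisher's
#' exact test (two-sided).
#'
#' @param attenuated Logical vector, one entry per electrode.
#' @param region Character vector of region labels; every electrode must be
#'   PreCG or PostCG.
#' @return List: `table` (2x2 counts) and `p`.
#' @export
gyrus_contingency <- function(attenuated, region) {
  stopifnot(length(attenuated) == length(region))
  if (length(attenuated) == 0L)
    stop("gyrus_contingency: empty electrode set", call. = FALSE)
  if (!all(region %in% c("PreCG", "PostCG")))
    stop("gyrus_contingency: every electrode must be PreCG or PostCG",
         call. = FALSE)
  tab <- table(factor(region, levels = c("PreCG", "PostCG")),
               factor(attenuated, levels = c(TRUE, FALSE)))
  tab <- matrix(as.integer(tab), 2, 2,
                dimnames = list(region = c("PreCG", "PostCG"),
                                attenuated = c("yes", "no")))
  fisher_exact(tab)
}

#' Distances to the hand-knob reference point
#'
#' Euclidean distance (mm) from every electrode to the deepest point of the
#' hand knob ("sigma") of its hemisphere; hemisphere is taken from the sign
#' of the electrode's x coordinate (MNI RAS: x < 0 left). Electrodes at
#' x = 0 are assigned the configured default hemisphere with a warning.
#'
#' @param electrodes An [electrode_table()].
#' @param sigma_left,sigma_right 3-vectors (x, y, z) in mm of the left and
#'   right hand-knob points.
#' @param default_hemisphere Hemisphere used for x = 0 electrodes.
#' @return Named numeric vector of distances (mm).
#' @export
handknob_distances <- function(electrodes,
                               sigma_left = c(-36, -22, 54),
                               sigma_right = c(36, -22, 54),
                               default_hemisphere = c("left", "right")) {
  default_hemisphere <- match.arg(default_hemisphere)
  stopifnot(length(sigma_left) == 3L, length(sigma_right) == 3L)
  if (any(electrodes$x == 0))
    warning("electrode(s) at x = 0 assigned to the ", default_hemisphere,
            " hemisphere: ",
            paste(electrodes$name[electrodes$x == 0], collapse = ", "),
            call. = FALSE)
  left <- electrodes$x < 0 | (electrodes$x == 0 & default_hemisphere == "left")
  sig <- t(vapply(left, function(l) if (l) sigma_left else sigma_right,
                  numeric(3)))
  d <- sqrt((electrodes$x - sig[, 1])^2 + (electrodes$y - sig[, 2])^2 +
              (electrodes$z - sig[, 3])^2)
  stats::setNames(d, electrodes$name)
}

#' Hand-knob distance comparison between attenuated and non-attenuated
#' electrodes
#'
#' Two-sided Mann-Whitney U test on the hand-knob distances of attenuated
#' vs non-attenuated electrodes.
#'
#' @param distances Named numeric vector (mm), e.g. from
#'   [handknob_distances()].
#' @param attenuated Logical vector aligned with `distances`.
#' @return List: `U`, `p`, `median_attenuated`, `median_non`, sample sizes.
#' @export
distance_attenuation_test <- function(distances, attenuated) {
  stopifnot(length(distances) == length(attenuated))
  d_att <- distances[attenuated]; d_non <- distances[!attenuated]
  mw <- mann_whitney(d_att, d_non)
  list(U = mw$U, p = mw$p,
       median_attenuated = stats::median(d_att),
       median_non = stats::median(d_non),
       n_attenuated = length(d_att), n_non = length(d_non))
}
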