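#' Body-part vocabulary
#'
#' Occupational health protection profiles report deviations of functional
#' work ability against a fixed vocabulary of fourteen body parts: two
#' midline parts (neck, trunk) and six paired parts (shoulder, elbow, wrist,
#' fingers, knee, foot), each with a left and a right side.
#'
#' @return A data.frame with columns `part` (canonical id such as
#'   `"shoulder_L"`), `region` and `side` (`"L"`, `"R"` or `"none"`).
#' @examples
#' body_parts()
#' @export
body_parts <- function() {
  midline <- c("neck", "trunk")
  paired <- c("shoulder", "elbow", "wrist", "fingers", "knee", "foot")
  parts <- data.frame(
    region = c(midline, rep(paired, each = 2L)),
    side = c(rep("none", 2L), rep(c("L", "R"), times = length(paired))),
    stringsAsFactors = FALSE
  )
  parts$part <- ifelse(parts$side == "none", parts$region,
                       paste(parts$region, parts$side, sep = "_"))
  parts[, c("part", "region", "side")]
}

#' Canonical body-part ids
#'
#' @return Character vector of the 14 part ids in canonical order
#'   (neck, trunk, then paired parts left before right).
#' @export
part_ids <- function() body_parts()$part

#' Protection levels
#'
#' `MN` ("must not use") denotes a more severe restriction than `SN`
#' ("should not use").
#'
#' @return Character vector `c("MN", "SN")`.
#' @export
protection_levels <- function() c("MN", "SN")

#' 28-flag column schema
#'
#' The flat profile table splits each body part into one column per
#' protection level, giving 28 ordered binary columns such as
#' `neck_MN`, `neck_SN`, ..., `foot_R_SN`.
#'
#' @return Character vector of the 28 flag column names in canonical order.
#' @export
flag_columns <- function() {
  as.vector(t(outer(part_ids(), protection_levels(), paste, sep = "_")))
}
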