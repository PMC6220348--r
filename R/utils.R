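#' Wrap angles to the half-open interval (-180, 180]
#'
#' Model arithmetic is linear (angles stay well within +/-90 degrees); wrapping
#' is applied only at the analysis boundary, e.g. when differencing target and
#' shooting angles.
#'
#' @param x numeric vector of angles in degrees.
#' @return Angles wrapped to `(-180, 180]`.
#' @examples
#' wrap_angle(c(270, -340, 180, -180))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180 & !is.na(w)] <- w[w > 180 & !is.na(w)] - 360
  w
}

# Deterministic child seed in [1, 2^31 - 2] derived from a master seed and one
# or more integer tags; splits one master seed into independent streams.
child_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + (t %% 2147483647) + 1) %% 2147483647
  as.integer(h %% 2147483646L) + 1L
}

# 32-bit FNV-1a hash of a character scalar, hex-encoded; used for run manifests.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor the low byte only (b < 256); keeps h a double within 2^32
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply via 16-bit split (stays exact in doubles)
    h <- (((h %/% 65536 * prime) %% 65536) * 65536 + (h %% 65536) * prime) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
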