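#' Dower lead transformation matrices
#'
#' Fixed linear maps between the eight independent ECG leads
#' (I, II, V1--V6) and the orthogonal vectorcardiographic leads X, Y, Z.
#' `dower_inverse()` returns the 3 x 8 inverse Dower matrix (rows X, Y, Z);
#' `dower_forward()` returns the published 8 x 3 Dower matrix projecting a
#' dipole onto the leads. The two are rounded pseudo-inverses of each other,
#' so `dower_inverse() %*% dower_forward()` is close to, but not exactly,
#' the identity.
#'
#' @return Numeric matrix with dimnames; lead order `I, II, V1..V6`.
#' @export
dower_inverse <- function() {
  m <- rbind(
    X = c(-0.172, -0.074, 0.122, 0.231, 0.239, 0.194, 0.156, -0.010),
    Y = c( 0.057, -0.019, -0.106, -0.022, 0.041, 0.048, -0.227, 0.887),
    Z = c(-0.229, -0.310, -0.246, -0.063, 0.055, 0.108, 0.022, 0.102)
  )
  colnames(m) <- c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II")
  m[, tvv_lead_order()]
}

#' @rdname dower_inverse
#' @export
dower_forward <- function() {
  m <- rbind(
    I  = c( 0.632, -0.235,  0.059),
    II = c( 0.235,  1.066, -0.132),
    V1 = c(-0.515,  0.157, -0.917),
    V2 = c( 0.044,  0.164, -1.387),
    V3 = c( 0.882,  0.098, -1.277),
    V4 = c( 1.213,  0.127, -0.601),
    V5 = c( 1.125,  0.127, -0.086),
    V6 = c( 0.831,  0.076,  0.230)
  )
  colnames(m) <- c("X", "Y", "Z")
  m
}

#' Canonical order of the eight independent leads
#' @return Character vector `c("I","II","V1",...,"V6")`.
#' @export
tvv_lead_order <- function() c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Inverse Dower transformation
#'
#' Maps amplitudes of the eight independent leads to the 3-D heart vector.
#' Pure linear map; operates on a single 8-vector or on an
#' `n x 8` matrix of samples (columns named or ordered `I, II, V1..V6`).
#'
#' @param leads Numeric 8-vector or `n x 8` matrix of lead amplitudes in mV.
#' @return Numeric 3-vector `(X, Y, Z)` or `n x 3` matrix, in mV.
#' @examples
#' inverse_dower(c(0, 1, 0, 0, 0, 0, 0, 0))  # lead II = 1 mV
#' @export
inverse_dower <- function(leads) {
  D <- dower_inverse()
  if (is.matrix(leads)) {
    stopifnot(ncol(leads) == 8L)
    if (!is.null(colnames(leads))) leads <- leads[, tvv_lead_order(), drop = FALSE]
    if (any(!is.finite(leads))) stop("non-finite lead amplitudes")
    out <- leads %*% t(D)
    colnames(out) <- c("X", "Y", "Z")
    return(out)
  }
  stopifnot(length(leads) == 8L)
  if (!is.null(names(leads))) leads <- leads[tvv_lead_order()]
  if (any(!is.finite(leads))) stop("non-finite lead amplitudes")
  drop(D %*% leads)
}

#' Forward Dower projection of a dipole onto the eight leads
#'
#' @param xyz Numeric 3-vector or `n x 3` matrix (X, Y, Z in mV).
#' @return 8-vector or `n x 8` matrix of lead amplitudes, ordered `I, II, V1..V6`.
#' @export
forward_dower <- function(xyz) {
  G <- dower_forward()
  if (is.matrix(xyz)) {
    stopifnot(ncol(xyz) == 3L)
    out <- xyz %*% t(G)
    colnames(out) <- rownames(G)
    return(out)
  }
  stopifnot(length(xyz) == 3L)
  drop(G %*% xyz)
}
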