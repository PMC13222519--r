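# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

rk_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "residuekit_error"), ...)
}

# Elements considered "ordinary organic" for the metal/coordination scope flag.
ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Se", "Br", "I")

# Periodic-table symbols, index = atomic number (through Og); used for the
# fingerprint atom invariants and for the SMILES atom lexer.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

atomic_number <- function(symbol) {
  match(symbol, ELEMENT_SYMBOLS)
}

# Deterministic integer hash of an integer vector, kept below 2^31 so it stays
# exactly representable; used by the circular fingerprint and parity ranking.
hash_ints <- function(x) {
  h <- 7
  for (v in x) {
    h <- (h * 31 + (v %% 2147483647L) + 2147483647L) %% 2147483647
  }
  as.integer(h)
}

# vectorised Euclidean distance between two xyz rows
vec_dist <- function(a, b) sqrt(sum((a - b)^2))

# angle at b (degrees) for points a-b-c
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# signed dihedral (degrees, in (-180, 180]) for points p1-p2-p3-p4
vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  normalize_angle(ang)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# map any angle in degrees to (-180, 180]
normalize_angle <- function(x) {
  x <- x %% 360
  ifelse(x > 180, x - 360, x)
}

# NeRF-style placement: position of atom D given A-B-C, |CD|, angle(B,C,D)
# and dihedral(A,B,C,D) in degrees.
place_atom <- function(a, b, c, dist, angle, dihedral) {
  angle <- angle * pi / 180
  dihedral <- -dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-dist * cos(angle),
          dist * sin(angle) * cos(dihedral),
          dist * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
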