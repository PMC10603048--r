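# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# xyz vector (x1,y1,z1,x2,...) <-> N x 3 matrix
xyz_to_mat <- function(xyz) matrix(xyz, ncol = 3, byrow = TRUE)
mat_to_xyz <- function(m) as.numeric(t(m))

deg2rad <- function(x) x * pi / 180

aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN", E = "GLU",
  G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS", M = "MET", F = "PHE",
  P = "PRO", S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa_one <- structure(names(aa_three), names = aa_three)

water_resids <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD", "H2O")

is_standard_aa <- function(resid) resid %in% aa_three

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
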