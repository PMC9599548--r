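# Amino-acid alphabets, property scales and class partitions used by the
# descriptor families. All scales are published per-residue tables; they are
# package data, pinned here so featurization is fully reproducible offline.

# Alphabetical order used for all sequence-derived feature columns.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column order of the PSI-BLAST ASCII PSSM dialect.
AA20_PSSM <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues mapped to X during canonicalization (plus gaps and stops).
NONCANONICAL <- c("B", "Z", "J", "U", "O", "X", "*", "-", ".")

.scale <- function(...) {
  v <- c(...)
  stopifnot(identical(sort(names(v)), sort(AA20)))
  v[AA20]
}

# Eight per-residue numeric property scales (autocorrelation + sequence-order
# families). Values are the classical published tables.
AA_SCALES <- list(
  # Kyte-Doolittle hydropathy
  hydropathy = .scale(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                      L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
  # Hopp-Woods hydrophilicity
  hydrophilicity = .scale(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
                          Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8,
                          L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
                          S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
  # Grantham polarity
  polarity = .scale(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5,
                    Q = 10.5, E = 12.3, G = 9.0, H = 10.4, I = 5.2,
                    L = 4.9, K = 11.3, M = 5.7, F = 5.2, P = 8.0,
                    S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9),
  # Charton-Charton polarizability
  polarizability = .scale(A = 0.046, R = 0.291, N = 0.134, D = 0.105,
                          C = 0.128, Q = 0.180, E = 0.151, G = 0.000,
                          H = 0.230, I = 0.186, L = 0.186, K = 0.219,
                          M = 0.221, F = 0.290, P = 0.131, S = 0.062,
                          T = 0.108, W = 0.409, Y = 0.298, V = 0.140),
  # free-residue molecular weight
  mass = .scale(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
                Q = 146.15, E = 147.13, G = 75.07, H = 155.16, I = 131.17,
                L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
                S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15),
  # Zamyatnin residue volume
  volume = .scale(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                  Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                  S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0),
  # Bhaskaran-Ponnuswamy average flexibility
  flexibility = .scale(A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346,
                       Q = 0.493, E = 0.497, G = 0.544, H = 0.323, I = 0.462,
                       L = 0.365, K = 0.466, M = 0.295, F = 0.314, P = 0.509,
                       S = 0.507, T = 0.444, W = 0.305, Y = 0.420, V = 0.386),
  # isoelectric point of the free amino acid
  pI = .scale(A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.07,
              Q = 5.65, E = 3.22, G = 5.97, H = 7.59, I = 6.02,
              L = 5.98, K = 9.74, M = 5.74, F = 5.48, P = 6.30,
              S = 5.68, T = 5.60, W = 5.89, Y = 5.66, V = 5.96)
)

# Standardize a scale to mean 0, sd 1 over the 20 letters (population sd).
standardize_scale <- function(s) {
  m <- mean(s)
  sd0 <- sqrt(mean((s - m)^2))
  (s - m) / sd0
}

# Classical 7-property, 3-class partitions for composition/transition/
# distribution descriptors (Dubchak-style groupings).
CTD_PARTITIONS <- list(
  hydrophobicity = list(polar = c("R", "K", "E", "D", "Q", "N"),
                        neutral = c("G", "A", "S", "T", "P", "H", "Y"),
                        hydrophobic = c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(small = c("G", "A", "S", "C", "T", "P", "D"),
                    medium = c("N", "V", "E", "Q", "I", "L"),
                    large = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(low = c("L", "I", "F", "W", "C", "M", "V", "Y"),
                  medium = c("P", "A", "T", "G", "S"),
                  high = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(low = c("G", "A", "S", "D", "T"),
                        medium = c("C", "P", "N", "V", "E", "Q", "I", "L"),
                        high = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(positive = c("K", "R"),
                neutral = c("A", "N", "C", "Q", "G", "H", "I", "L", "M",
                            "F", "P", "S", "T", "W", "Y", "V"),
                negative = c("D", "E")),
  secondary_structure = list(helix = c("E", "A", "L", "M", "Q", "K", "R", "H"),
                             strand = c("V", "I", "Y", "C", "W", "F", "T"),
                             coil = c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(buried = c("A", "L", "F", "C", "G", "I", "V", "W"),
                               exposed = c("P", "K", "Q", "E", "N", "D"),
                               intermediate = c("M", "R", "S", "T", "H", "Y"))
)

# Shen 7-class alphabet for conjoint-triad descriptors.
TRIAD_CLASSES <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
                      c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
                      c("R", "K"), c("D", "E"), c("C"))

# 5-group physicochemical alphabet for grouped compositions.
AA_GROUPS5 <- list(aliphatic = c("G", "A", "V", "L", "M", "I"),
                   aromatic = c("F", "Y", "W"),
                   positive = c("K", "R", "H"),
                   negative = c("D", "E"),
                   uncharged = c("S", "T", "C", "P", "N", "Q"))

# Codon multiplicities of the standard genetic code (dipeptide deviation
# from expected mean descriptor).
CODON_COUNTS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                  K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                  T = 4, V = 4, W = 1, Y = 2)

# 10-group reduced alphabet for the reduced-PSSM transform.
RPSSM_GROUPS <- list(c("F", "Y", "W"), c("M", "L"), c("I", "V"),
                     c("A", "T", "S"), c("C"), c("G"), c("P"),
                     c("H", "N", "Q"), c("D", "E"), c("R", "K"))

# Pairwise residue distance matrices derived from the standardized property
# scales: one from the hydro-set (hydropathy, hydrophilicity, polarity), one
# from the steric-set (volume, mass, polarizability). Used by the
# sequence-order coupling descriptors.
.scale_distance <- function(scale_names) {
  z <- sapply(AA_SCALES[scale_names], standardize_scale)
  d <- as.matrix(stats::dist(z))
  dimnames(d) <- list(AA20, AA20)
  d
}

aa_distance_matrices <- function() {
  list(hydro = .scale_distance(c("hydropathy", "hydrophilicity", "polarity")),
       steric = .scale_distance(c("volume", "mass", "polarizability")))
}
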