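# Shared fixtures: a PBS-like buffer at 4 C, a 17-kDa coiled-coil-sized
# test species, and a coarse radial grid (61 points) that keeps fits fast
# without changing the physics.

pbsBuffer <- function(tempK = 277) bufferSpec(density = 1.005,
                                              temperature = tempK)

ccSpecies <- function(mass = 17000, vbar = 0.726, n = 150)
  species("cc", mass, vbar, extinction230(n))

coarseGrid <- seq(6.85, 7.15, by = 0.005)

# random sequences over the 20 standard residues
randomSeq <- function(n)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
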