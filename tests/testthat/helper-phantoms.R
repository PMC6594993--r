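# Programmatic phantoms shared across the suite. All are built in code at
# test time; nothing is read from disk.

# A straight cylinder crossing the whole volume along x, centered in y/z.
cylinderTree <- function(shape, radius) {
  cy <- (shape[2] - 1) / 2
  cz <- (shape[3] - 1) / 2
  SwcTree(data.frame(id = 1:2, type = 3L,
                     x = c(0, shape[1] - 1), y = cy, z = cz,
                     radius = radius, parent = c(-1L, 1L)),
          c(1, 1, 1))
}

# Noise-free analog of a fluorescence stack: occupancy scaled to 8 bits.
noiseFreeVolume <- function(tree, shape, supersample = 3) {
  occ <- voxelizeTree(tree, shape,
                      simulationParams(4, supersample = supersample,
                                       voxelAspect = c(1, 1, 1)))
  IntensityVolume(255 * volumeData(occ), c(1, 1, 1))
}

# The Y morphology and stack size used by the end-to-end experiments.
yPhantom <- function() generateToyTree("Y", length = 60, radius = 2,
                                       origin = c(8, 32, 12))
yShape <- c(72, 64, 24)

simulateY <- function(snr, seed, cor = 0) {
  simulateStack(yPhantom(), yShape,
                simulationParams(snr = snr, cor = cor, seed = seed,
                                 voxelAspect = c(1, 1, 1)))$volume
}
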