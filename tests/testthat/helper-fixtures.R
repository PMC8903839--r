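# shared fixtures: small materials and geometries used across test files

# the packaged hydrogel preset
mat_table1 <- table1_material()

# elastic poroelastic material (no Prony branches) for analytic benchmarks
mat_elastic <- function(permeability = 2.1e-14) {
  material_properties(E_eq = 500e3, nu = 0.23, porosity = 0.68,
                      permeability = permeability, biot_alpha = 1,
                      C_solid = 1308, K_solid = 0.25,
                      C_fluid = 4200, K_fluid = 0.6)
}

# single-branch Prony with unit-friendly numbers
prony_1b <- prony_series(g_inf = 1e5, G = 5e4, tau = 2)

# effective thermal properties of the sample mixture
sample_rhoC <- function(m) {
  m$porosity * m$rho_fluid * m$C_fluid +
    (1 - m$porosity) * m$rho_solid * m$C_solid
}
sample_K <- function(m) m$porosity * m$K_fluid + (1 - m$porosity) * m$K_solid

# plain triangle areas of a mesh (independent of the package's internals)
tri_geometry_for_test <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  list(area = abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2)
}
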