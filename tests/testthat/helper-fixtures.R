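# Shared fixtures, built once per test run.  All geometry is generated in
# code; meshes are kept as coarse as the assertions allow.

rat_geo <- rat_lv_geometry()

# linear pre-P mesh, moderate resolution (geometry / microstructure tests)
fix_lv <- build_lv_mesh(rat_geo$pre_p, divisions = c(3, 16, 8))
fix_lv_frame <- material_axes(fix_lv)
fix_lv_w <- transmural_depth(fix_lv)

# concentric-spheres fixture (equal semi-axes pairs); fine enough in the
# angular directions for the surface-normal and volume oracles
sphere_spec <- ellipsoid_spec(c(1.2, 1.2, 1.2), c(1, 1, 1))
fix_sphere <- build_lv_mesh(sphere_spec, divisions = c(3, 48, 24))

# coarse quadratic mesh for mechanics solves
fix_mech <- build_lv_mesh(rat_geo$pre_p, divisions = c(2, 8, 4), order = 2)
fix_mech_sf <- build_structure_field(fix_mech, fibre = fibre_model(70, 1))

# max |u.v| deviation from orthonormality of a frame triple
frame_orthonormality_error <- function(f, s, n) {
  max(abs(cbind(rowSums(f * s), rowSums(f * n), rowSums(s * n),
                rowSums(f * f) - 1, rowSums(s * s) - 1,
                rowSums(n * n) - 1)))
}

frame_det <- function(f, s, n) {
  f[, 1] * (s[, 2] * n[, 3] - s[, 3] * n[, 2]) -
    f[, 2] * (s[, 1] * n[, 3] - s[, 3] * n[, 1]) +
    f[, 3] * (s[, 1] * n[, 2] - s[, 2] * n[, 1])
}

# rotation matrix about a unit axis
rot_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ca + sa * K + (1 - ca) * tcrossprod(a)
}
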