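# lumensim

Cell-resolved simulation of early bile-duct lumen formation.

## The problem

In the embryonic liver, bile ducts begin as single lumina that open
between two cell layers next to the portal vein: an inner layer of
cholangiocytes (biliary epithelial cells, differentiating from bipotent
hepatoblasts) facing the portal mesenchyme, and an outer layer of
hepatoblasts. Three mechanical mechanisms could drive this cord-hollowing
event: oriented cell division of the polarized cholangiocytes,
actomyosin-driven apical constriction, and osmotic pressure generated by
apical ion secretion into the nascent cavity. `lumensim` is a tool for
testing these mechanisms in silico, alone and combined, in both an
idealized two-layer system and a portal-vein cross-section.

## The model

Cells near the forming lumen are deformable rings of viscoelastic cortex
elements (a deformable cell model, DCM). Each node obeys an overdamped
force balance

```
Gamma_i v_i = F_elastic + F_bending + F_volume + F_adhesion + F_repulsion
            + F_migration + F_osmotic
```

with diagonal node friction, cortex-sheet springs (E_cor h_cor), a
turning-angle bending penalty, volume control p = K_V (1 - A/A_ref), a
cohesive-zone (Dugdale-type) adhesion/repulsion law whose work of
separation per contact area is the region-dependent adhesion energy
(apical W_ap = 1e-6, tight-junction 10 W, elsewhere W = 9e-4 J/m^2), a
Brownian motility force calibrated to the cell diffusion constant, and a
constant lumen pressure P_L on surface elements marked by secreted
tracer particles. Cells are polarized (apico-basal and planar polarity
vectors), grow linearly to double volume over a 24 h cycle, divide
through a five-stage algorithm (round-up, plane choice, confined
daughter growth, envelope removal), differentiate from hepatoblast to
cholangiocyte on a 2 h contact-and-lumen signalling timer, and are held
at the measured cycling fractions (26.0% of cholangiocytes, 10.7% of
hepatoblasts) by a proliferation-rate controller. Surrounding tissue
(fixed portal-vein endothelium, far-field hepatoblasts) is carried by a
center-based model with a modified Johnson-Kendall-Roberts contact law
calibrated against a deformable-cell pair; both representations interact
mechanically. See `vignette("lumenogenesis")` for the full account.

## A worked example

A reduced idealized-bilayer run in which four secreting cholangiocytes
open a cavity by osmotic pressure (50 Pa) between two cell layers:

```r
library(lumensim)
cfg <- default_config()
cfg$dcm$n_nodes <- 36            # reduced ring resolution
run <- run_bilayer("osmosis", cfg, seed = 1, duration = 6)
tail(run$series[, c("time", "area", "n_marked", "n_extr")], 3)
#>    time     area n_marked n_extr
#> 23  5.5 317.5 ...
#> 24  5.75 ...
#> 25  6.0  367.3 ...
measure_lumen(run)
#> <lumen: t = 6.00 h, area = 367.3 um^2, ... lining cells (4 cholangiocytes)>
```

`run$series` is the measured time series: `area` is the cavity area in
um^2 found by tracing the free boundary between the cell rings,
`n_marked` the number of osmotically loaded surface elements and
`n_extr` the number of luminal tracer particles. An area of a few
hundred um^2 after a few hours corresponds to a cavity of roughly one
cell cross-section, the scale seen in nascent ducts. The portal-vein
system runs the same way:

```r
run <- run_model(3, cfg, seed = 1, duration = 24)   # full model, P_L = 50 Pa
plot(run$series$time, run$series$area, type = "l",
     xlab = "time after first cholangiocyte (h)", xlim = c(0, 24),
     ylab = "lumen area (um^2)")
write_vtk(run, "duct.vtk")      # polygons + spheres for ParaView
```

Model variants 0-3 (`model_variant()`) switch oriented division, apical
constriction and osmosis on and off; `P_L` and `T_sig` are arguments.
Shell entry points live in `inst/scripts/` (`run-duct.R`,
`run-bilayer.R`).

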