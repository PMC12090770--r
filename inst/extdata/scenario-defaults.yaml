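# Package-wide scenario defaults. Every default used by simulationConfig()
# and readScenario() lives here, nowhere else. Units: lengths um, time h,
# concentrations mM, mass pg, fluxes mmol/gDW/h, diffusivities um^2/h.
cellSize: 10          # lattice resolution
slabDepth: 10         # out-of-plane depth giving 2D cells a volume
dryWeightFraction: 0.3  # gDW per g wet mass
cellDensity: 1.1      # agent wet density, pg/um^3
stepLength: 5         # planktonic step per timestep
rotationSd: 30        # planktonic heading rotation SD, degrees
divisionThreshold: 2  # division size threshold
divisionOn: radius    # threshold applies to radius (um) or mass (pg)
dt: 0.1               # timestep
maxSteps: 200
steadyTol: 0.001      # max relative change over the window
steadyWindow: 20      # sliding window, steps
seed: 1
outputInterval: 10
shoveMaxIter: 10      # shoving repetition cap per phase
fvaFraction: 0.9      # suboptimal FVA objective fraction
planktonicFBA: true   # unattached agents also feed from their cell
sourceIterations: 1   # flux/field fixed-point couplings per step
biofilmFactor: 0.6    # diffusivity multiplier inside biofilm
kineticsDefaults:
  vmax: 10            # saturating uptake, mmol/gDW/h
  km: 0.01            # half-saturation, mM
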