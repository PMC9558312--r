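# Titration of an ideal aspartate-like reference site.
# Run:  Rscript inst/scripts/lambdacph.R titrate example-titration.yaml --out out/
mode: titrate
seed: 11
output: lambdacph_out
system:
  fixture:
    kind: ideal_site
    pKaRefs: [3.65]
integrator:
  dt: 0.01
  nSteps: 200000
  lambdaT: 300
  lambdaTau: 2.0
  outputInterval: 1.0
potentials:
  barrier: 5.0
titration:
  pH: [1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 6.5, 7.0]
  replicas: 5
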