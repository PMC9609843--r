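# Sliding-mode reproduction run: 200 -> 70 mg/dL on the reference plant.
plant = "printed_tf"
controller = "smc"
G_ref = 70
G0 = 200
dt = 0.01
horizon = 100
settling_band = 0.02
integrator = "rk4"
seed = 1

[smc]
c1 = 1
c2 = 2.5
c3 = 1
k1 = 6
k2 = 9
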