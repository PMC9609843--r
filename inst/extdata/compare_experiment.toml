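# Three-controller comparison on the reference plant.
plant = "printed_tf"
G_ref = 70
G0 = 200
dt = 0.01
horizon = 600
settling_band = 0.02
integrator = "rk4"
seed = 1

[pid]
kp = -0.000151
ki = -0.0000000275
kd = -0.207

[lqr]
Q = [0.001, 0, 0, 0, 0.2341, 0, 0, 0, 0.22]
R = 1

[smc]
c1 = 1
c2 = 2.5
c3 = 1
k1 = 6
k2 = 9
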