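r_x: 1.14030500048245
r_y: 1.16288596988862
a_x: 0.040357375881601099
a_y: 0.040357375881601099
A_x: 24778617.988785099
A_y: 24778617.988785099
d_x0: 0.00040000000000000002
d_y0: 0.00040000000000000002
d_x1: 1
d_y1: 1
r_m: 1.6696470049326799e-08
c_xx: 0.01
c_xy: 0.01
c_yx: 0.01
c_yy: 0.01
r_s: 0.020714285714285699
e_s: 5.9556786703601103
e_a: 3957261.5765730101
I_base: 7
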