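side,sphere,x_mm,y_mm,z_mm,radius_mm
right,1,18,11.9,8.2,30
right,2,171,1.4,24.9,15
right,3,139,1.5,38.6,15
left,4,6,3,3.9,30
left,5,184.5,0.8,23.8,15
left,6,142.6,4.5,40.0,15
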