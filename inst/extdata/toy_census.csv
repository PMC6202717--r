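# synthetic two-cluster toy census (generated, not field data)
label,mass
sp01,20.623
sp02,13.32
sp03,19.769
sp04,19.167
sp05,10.119
sp06,14.375
sp07,14.646
sp08,21.659
sp09,22.938
sp10,15.08
sp11,19.405
sp12,15.67
sp13,14.482
sp14,7.89
sp15,17.959
sp16,1905.783
sp17,2752.574
sp18,1940.198
sp19,3056.776
sp20,2589.613
sp21,3693.061
sp22,2623.237
sp23,7056.415
sp24,1344.205
sp25,3216.271
sp26,2606.663
sp27,1851.987
sp28,4340.378
sp29,2718.404
sp30,2773.192
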