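dataset,scenario,system,rmse,mae,mape,r2,mcc,se_lt_05,ase
2018,559 PH30,IL,19.36,13.45,8.79,91.71,81.08,89.96,0.189
2018,559 PH30,AL,18.87,13.29,8.65,92.12,80.01,90.29,0.185
2018,559 PH30,CL,19.05,13.17,8.78,91.97,80.68,89.52,0.184
2018,559 PH30,ACL,18.77,13.09,8.55,92.20,81.37,89.60,0.184
2018,559 PH60,IL,33.22,25.08,17.97,75.58,64.43,75.78,0.350
2018,559 PH60,AL,32.54,23.88,16.19,76.57,65.57,78.67,0.329
2018,559 PH60,CL,32.07,24.26,16.00,75.80,65.27,78.11,0.327
2018,559 PH60,ACL,32.54,24.12,16.55,76.57,64.71,77.43,0.336
2018,563 PH30,IL,19.68,13.37,8.23,81.81,74.17,91.68,0.183
2018,563 PH30,AL,19.05,14.02,8.19,80.42,73.46,91.64,0.188
2018,563 PH30,CL,19.17,13.61,8.13,81.75,73.60,91.56,0.187
2018,563 PH30,ACL,18.75,13.05,8.15,82.37,77.10,91.95,0.182
2018,563 PH60,IL,29.97,21.87,13.81,57.81,57.97,81.23,0.305
2018,563 PH60,AL,30.57,22.06,13.65,56.11,56.61,80.71,0.301
2018,563 PH60,CL,30.65,21.99,13.63,55.88,56.99,80.52,0.301
2018,563 PH60,ACL,31.04,22.64,13.65,54.73,53.13,79.50,0.306
2018,570 PH30,IL,16.25,11.41,5.68,94.05,86.49,96.44,0.107
2018,570 PH30,AL,16.08,11.25,5.73,94.17,86.80,96.40,0.109
2018,570 PH30,CL,16.47,11.21,5.60,93.88,86.79,96.62,0.105
2018,570 PH30,ACL,15.86,11.07,5.58,94.18,86.73,96.58,0.104
2018,570 PH60,IL,29.89,22.26,10.91,79.86,75.79,89.89,0.203
2018,570 PH60,AL,28.38,20.65,10.31,81.85,76.76,90.11,0.193
2018,570 PH60,CL,27.37,19.94,10.39,83.10,77.55,90.26,0.193
2018,570 PH60,ACL,27.5,20.05,10.48,82.95,77.88,90.41,0.195
2018,575 PH30,IL,23.01,14.34,10.13,85.59,76.08,86.37,0.222
2018,575 PH30,AL,23.00,14.85,10.54,83.91,77.23,88.00,0.224
2018,575 PH30,CL,22.45,15.11,10.16,86.28,77.31,86.75,0.219
2018,575 PH30,ACL,22.52,15.16,10.03,86.20,77.81,86.99,0.217
2018,575 PH60,IL,36.82,26.30,18.90,63.12,52.24,70.89,0.396
2018,575 PH60,AL,36.25,25.97,18.80,66.26,52.37,71.80,0.395
2018,575 PH60,CL,35.15,25.57,19.38,66.09,54.11,70.85,0.398
2018,575 PH60,ACL,36.55,26.07,19.07,64.65,52.02,70.03,0.397
2018,588 PH30,IL,19.25,13.78,8.29,83.95,71.09,92.02,0.183
2018,588 PH30,AL,18.81,13.67,8.14,84.67,73.05,91.91,0.198
2018,588 PH30,CL,18.41,13.58,8.16,85.32,75.24,92.02,0.184
2018,588 PH30,ACL,18.72,13.64,8.25,84.82,76.24,91.73,0.182
2018,588 PH60,IL,31.04,23.06,14.18,58.25,59.40,78.17,0.309
2018,588 PH60,AL,30.92,22.63,13.90,56.56,57.36,80.05,0.277
2018,588 PH60,CL,31.19,22.97,13.62,58.56,58.36,79.07,0.303
2018,588 PH60,ACL,31.75,23.14,13.56,56.32,56.01,80.30,0.289
2018,591 PH30,IL,21.13,15.61,11.95,81.92,62.66,82.79,0.264
2018,591 PH30,AL,21.41,15.24,11.83,82.46,65.11,82.61,0.262
2018,591 PH30,CL,21.22,15.68,11.63,82.77,63.59,82.90,0.259
2018,591 PH30,ACL,21.25,15.49,12.13,82.73,62.97,82.10,0.268
2018,591 PH60,IL,33.48,25.88,21.08,57.11,44.65,68.38,0.418
2018,591 PH60,AL,32.75,25.15,20.75,58.19,44.61,69.12,0.407
2018,591 PH60,CL,33.20,25.53,19.73,58.96,45.69,69.23,0.418
2018,591 PH60,ACL,33.00,25.45,20.08,58.98,46.52,69.44,0.413
2020,540 PH30,IL,21.49,15.93,11.81,89.72,73.84,81.05,0.228
2020,540 PH30,AL,20.90,15.63,11.17,90.01,74.46,82.54,0.238
2020,540 PH30,CL,21.68,16.08,11.02,89.58,74.70,81.98,0.231
2020,540 PH30,ACL,21.18,15.75,11.07,90.26,73.98,84.69,0.234
2020,540 PH60,IL,40.10,30.59,21.71,64.88,53.71,61.20,0.424
2020,540 PH60,AL,38.76,29.77,21.96,65.54,56.92,62.85,0.419
2020,540 PH60,CL,39.01,30.06,21.20,65.50,54.88,65.12,0.416
2020,540 PH60,ACL,38.84,29.48,20.67,66.43,57.62,64.51,0.404
2020,544 PH30,IL,18.02,13.06,8.94,88.61,79.21,91.15,0.192
2020,544 PH30,AL,17.99,12.70,8.35,88.74,79.45,91.60,0.180
2020,544 PH30,CL,17.98,12.61,8.23,88.74,79.67,92.08,0.175
2020,544 PH30,ACL,18.01,12.72,8.21,88.72,79.69,91.89,0.174
2020,544 PH60,IL,31.39,23.65,16.05,65.71,58.59,74.03,0.336
2020,544 PH60,AL,30.93,23.21,15.83,66.72,60.77,75.14,0.328
2020,544 PH60,CL,30.85,23.25,16.01,66.88,61.05,75.07,0.333
2020,544 PH60,ACL,31.47,23.92,16.65,65.54,61.25,74.70,0.341
2020,552 PH30,IL,16.73,12.50,9.70,89.71,74.76,89.40,0.205
2020,552 PH30,AL,16.78,12.50,9.51,89.65,74.98,89.87,0.202
2020,552 PH30,CL,16.89,12.66,9.70,89.52,75.14,89.40,0.205
2020,552 PH30,ACL,16.69,12.25,9.35,89.76,74.97,90.25,0.197
2020,552 PH60,IL,29.42,21.82,16.53,68.22,59.36,75.85,0.331
2020,552 PH60,AL,30.45,23.76,19.72,65.93,59.38,73.50,0.369
2020,552 PH60,CL,29.40,22.24,17.52,68.18,60.13,75.64,0.342
2020,552 PH60,ACL,28.96,22.18,17.71,69.02,61.41,75.55,0.341
2020,567 PH30,IL,20.68,14.74,11.01,85.76,64.45,82.42,0.258
2020,567 PH30,AL,21.11,15.25,11.45,85.02,62.95,81.81,0.268
2020,567 PH30,CL,20.88,14.98,11.18,85.34,64.03,82.24,0.260
2020,567 PH30,ACL,20.57,14.38,10.28,85.78,68.08,85.15,0.232
2020,567 PH60,IL,38.41,29.59,23.81,50.62,58.04,61.18,0.503
2020,567 PH60,AL,35.99,26.68,19.89,56.46,57.99,64.43,0.462
2020,567 PH60,CL,37.42,28.78,22.71,52.77,59.13,62.91,0.486
2020,567 PH60,ACL,36.93,27.72,21.26,54.09,58.03,66.04,0.440
2020,584 PH30,IL,21.78,15.83,10.56,87.18,77.08,88.02,0.211
2020,584 PH30,AL,22.35,16.12,11.20,86.40,77.28,87.54,0.229
2020,584 PH30,CL,21.32,15.24,9.89,87.52,78.05,89.24,0.203
2020,584 PH30,ACL,22.41,16.44,11.25,86.26,77.24,87.54,0.229
2020,584 PH60,IL,36.14,26.53,17.06,64.14,64.12,74.74,0.343
2020,584 PH60,AL,36.37,26.79,17.41,63.68,63.21,74.55,0.340
2020,584 PH60,CL,36.82,27.65,18.74,62.78,61.75,72.39,0.366
2020,584 PH60,ACL,36.04,26.55,17.34,64.34,63.27,74.85,0.343
2020,596 PH30,IL,17.92,12.75,9.54,87.83,75.67,88.81,0.203
2020,596 PH30,AL,17.68,12.44,9.28,87.70,74.33,89.07,0.209
2020,596 PH30,CL,17.42,12.11,8.84,88.04,74.58,89.40,0.193
2020,596 PH30,ACL,17.83,12.35,8.89,87.48,73.53,89.26,0.196
2020,596 PH60,IL,29.41,21.33,15.89,68.77,54.61,78.63,0.321
2020,596 PH60,AL,29.04,20.91,15.48,66.80,58.69,79.47,0.313
2020,596 PH60,CL,28.93,20.87,15.31,67.05,57.50,79.14,0.312
2020,596 PH60,ACL,29.21,20.99,15.10,66.41,56.29,79.44,0.311
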