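"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,18.08,20.8,24.46,27.2,31.77,40.24,44.61,50.23,54.03,66.1,73.48,77.7,83.15,89.65,91.94,92.61,94.62,26.29,31.33,35.02,41.8,48.76,67.63,73.42,76.76,80.56,90.77,57.39,57.11,57.21,56.88,50.1,52.82,57.52,61.38,65.71,45.37,40.79,33.4,29.48,32.75,37.94,82.13,80.34,74.67,69.39,74.1,84.34,72.33,69.1,64.99,58.1,51.73,45.85,41.84,42.01,47.86,56.69,66.56,69.81,67.55,62.16,57.72,49.8,47.55,47.67,58.25,62.48,49.75,57.92,68.78,77.38,84.92,87.3,90.28,96.1,93.8,97.02,93.25,87.88,81.84,76.83,66.33,58.34,52.13,30,28.37,28.85,28.44,29.99,30.73,28.55,26.63,27.56,29.22,38.03,42.81,48.43,53.18,58.28,58.89,59.53,59.37,59.33,39.52,36.4,36.03,38.62,40.77,41.9,37.86,35.7,37.42,39.72,41.52,40.03,72.54,69.97,65.64,62.85,68.31,69.29,74.99,77.94,80.01,81.93,80.73,78.66,74.54,70.35,67.23,70.56,74.22,77.03,75.43,78.07
2,19.83,19.6,23.28,24.95,31.14,35.78,41.66,49.95,55.44,64.21,71.2,77.85,84.72,89.14,91.28,93.2,95.27,25.8,32.33,34.77,40.62,46.07,66.66,72.54,77.05,82.61,87.86,57.55,55.44,57.16,57.01,50.23,51.77,58.33,59.42,64.92,44.2,39.4,34.49,30.5,32.08,41.29,82.67,81.35,75.19,70.81,73.45,80.34,72.41,69.55,63.08,57.06,49.87,42.63,41.46,42.56,49.84,56.21,65.05,68.94,66.72,64.68,56.82,47.64,44.12,48.86,57.5,62.16,45.85,56.59,66.04,72.34,80.42,84.95,88.58,93.41,91.8,91.68,90.5,86.8,80.9,72.83,63.98,55.85,47.91,26.29,25.67,25.27,24.57,29.04,28.2,24.36,24.3,25.98,27.14,34.71,41.24,45.13,53.98,57.39,58.77,59.07,56.21,54.96,37.46,35.32,33.56,37.24,36.35,37.52,35.65,32.51,33.42,37.23,38.5,38.27,70.1,65.09,63.62,61.58,63.42,67.99,71.55,75.67,75.83,78.56,76.59,76.41,70.24,67.16,69.22,70.39,71.41,73.94,74.05,74.14
3,20.19,21.72,24.18,25.63,33.58,37.34,43.25,50.79,57.01,66.64,71.72,79.22,83.21,90.03,90.37,95.03,95.1,24.84,31.21,35.56,41.77,46.48,68.42,74.23,77.78,82.14,87.2,56.98,57.33,56.98,58.7,47.37,52.78,57.44,61.44,65.27,44.81,40.29,34.25,30.85,33.94,39.82,83.18,81.37,75.2,70.39,73.43,80.02,73.87,72,66.25,58.53,51.28,43.66,42.43,44.16,49.7,57.55,65.82,71.56,68.14,64.19,58.06,50.44,47.2,49.76,56.61,63.87,50.46,60.6,67.04,75.86,83.92,87.31,92.56,93.28,94.39,93.62,90.85,89.16,81.97,76.61,66.43,56.27,50.03,27.34,28.51,26.4,27.96,31.62,30.12,27.64,27.62,28.02,28.16,36.32,43.08,48.25,55.25,59.33,59.96,61.24,59.73,57.95,37.82,35.53,35.32,37.25,40.81,41.47,38.72,37.32,35.63,38.52,40.45,39.56,73.26,67.99,63.82,66.01,65.61,68.57,70.82,75.81,80.6,82.24,79.71,76.23,71.67,70.2,68.61,71.4,73.54,76.61,76.72,76.76
4,17.1,19.14,22.29,24.29,28.45,32.86,42.17,48.12,52.23,63.22,68.4,75.05,83.3,85.32,89.96,91.61,91.7,23,29.37,33.71,39.7,43.72,62.82,72.13,73.31,79.68,84.95,55.59,55.44,54.24,56.04,49,49.71,55.93,58.72,63.6,42.7,38.17,31.21,28.43,29.49,37.15,81.51,78.7,71.94,68.22,72.4,79.49,71.5,67.58,61.23,55.79,47.74,41.73,37.31,41.17,46.43,56.48,62.79,68.16,67.17,61.06,55.36,47.65,44.47,47.73,55.11,61.66,46.87,56.55,65.03,74.4,81.24,86.11,88.47,90.61,92.54,92.65,89.46,85.69,80.06,73.04,63.33,56.65,47.7,26.11,24.25,25.6,26.79,28.16,27.4,25.15,26.08,24.82,26.8,34.35,40.69,45.89,51.15,56.49,57.79,58.46,57.78,57.05,37.47,33.75,35.07,37.51,38.4,38.7,36.11,34.21,33.35,35.64,36.94,37.97,72.01,66.78,65.5,63.08,65.44,67.35,72.09,78.3,78.65,79.89,79.65,75.53,73.2,67.46,68.14,71,73.33,75.73,76.29,75.25
5,17.15,18.27,24.47,24.49,30.81,35.05,42.83,47.63,55.28,63.53,70.21,75.71,82.9,87.53,89.42,94.48,93.83,25.59,32.58,35.08,40.09,44.72,66.6,73.33,75.24,80.83,87.96,55.49,54.52,58.29,55.09,47.28,51.69,56.25,60.55,63.33,42.88,39.44,32.04,29.39,31.92,39.21,83.99,78.91,74.15,70.57,71.39,81.41,72.51,68.97,64.38,55.34,48.37,42.81,40.27,42.63,48.14,55.89,65.41,71.69,66.54,63.08,56.8,48.7,46.87,48.55,55.94,62.89,50.53,59.84,69.45,76.03,83.1,88.44,90.34,95.94,95.4,94.37,92.67,86.55,81.21,75.36,65.62,58.92,48.99,30.53,27.92,27.5,28.74,29.99,27.55,27.28,27.3,30.05,28.78,38.66,45.71,49.81,57.2,60.45,60.42,60.4,59.88,59.26,39.15,34.55,35.19,36.69,40.28,40.25,39.17,34.94,36.01,37.04,41.2,40.35,72.56,69.89,66.43,64.29,66.28,69.32,73.43,76.9,80.29,80.67,78.81,74.72,72.52,70.22,70.6,72.31,73.18,74.76,76.63,75.78
6,18.28,19.13,19.07,24.4,27.22,33.98,41.67,47.44,53.95,62.72,69.4,74.34,81.3,87.53,89.65,92.71,93.94,22.76,30.64,33.7,39.5,46.27,64.67,70.62,75.89,81.27,86.06,54.53,54.7,55.6,55.48,46.95,52.2,55.33,59.03,64.28,41.58,39.84,31.63,27.52,32.35,38.77,82.14,78.88,72.42,68.34,72.11,78.78,73.75,68.34,62.7,55.35,48.9,40.54,38.17,40.74,47.5,54.7,64.38,70.81,66.01,60.92,56.37,48.98,44.39,46.75,53.02,61.44,51.91,60.26,68.87,75.22,82.82,89.41,93.88,95.09,96.57,95.66,94.22,89.17,82.37,76.19,69.26,59.25,52.26,31.12,27.98,29.35,29.46,31.05,30.46,30.12,28.91,28.08,31.52,38.03,44.69,51.3,56.64,60.51,60.51,64.16,61.11,60.09,41.62,37.42,37.9,39.85,41.65,42.52,39.56,37.6,37.28,39.57,44.91,41.58,75.21,72.37,66.72,65.78,69.91,69.04,75.9,80.1,82.68,83.88,83.88,79.57,75.07,70.06,70.61,72.48,75.51,79.58,77.84,79.26
7,15.63,16.8,19.9,21.84,26.72,33.48,40.29,45.39,50.7,59.72,67.33,75.09,78.8,84.27,87.36,88.72,90.81,21.6,27.68,31.58,35.9,43.33,64.88,70.24,75.06,76.62,83.58,52.37,52.55,53.17,52.39,44.5,47.52,54.77,56.78,61.38,40.83,35.09,31.2,25.44,28.08,37.21,80.95,76.65,70.57,66.59,70.31,76.76,69.2,65.68,59.79,53.07,46.34,38.88,37.76,39.68,45.18,52.09,60.97,66.71,63.34,58.12,52.93,45.97,41.58,45.42,52.35,60.43,48.17,59.75,67.53,74.1,83.3,86.63,90.86,95.14,93.38,92.55,91.08,88.71,82.07,74.67,65.6,56.41,50.51,29.2,24.97,26.66,28.79,29.17,28.64,26.64,26.85,27.29,29.3,36.01,41.91,47.29,54.31,57.49,58.25,60.47,58.18,58.5,39.5,34.57,35.99,37.17,40.17,41.15,38.85,36.44,36.51,37.44,41.34,37.55,71.97,67.18,66.44,64.74,65,67.93,72.3,76.95,81.13,79.86,77.98,74.68,71.07,68.73,66.93,70.1,73.55,77.85,75.99,75.69
8,18.54,22.14,23.69,24.07,31.3,36.05,43.55,48.92,56.25,64.35,70.45,76.15,82.81,89.66,90.43,92.11,94.28,26.5,32.7,36.33,43.21,44.6,66.84,72.74,75.6,83.38,87.75,56.04,55.74,55.39,55.52,47.26,52.02,57.24,60.52,64.36,44.58,38.91,33.28,29.65,32.42,39.22,83.3,78.71,74.03,69.81,72.68,83.1,73.91,70.2,64.33,57.14,48.52,42.7,41.06,42.41,47.96,56.05,65.96,72.29,69.22,61.18,57.29,49.91,44.4,47.42,57.36,64.04,50.88,58.18,70.12,75.47,83.39,86.92,92.87,94,94.56,94.83,92.62,88.07,81.48,76.07,67.15,58.64,49.49,29.51,27.32,28.09,29.91,29.3,29.68,26.79,28.88,27.69,29.3,39.64,43.03,48.69,56.03,58.72,60.23,61.14,59.23,58.67,39.51,36.48,35.15,37.51,42.39,39.87,37.81,35.79,36.14,40.73,42.35,40.74,71.45,68.42,65.49,65.6,65.88,70.09,72.61,76.22,79.67,82.93,80.95,78.5,73.71,69.25,68.09,70.06,74.62,77.09,76.72,76.8
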